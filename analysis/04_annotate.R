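#!/usr/bin/env Rscript
# Step 4 — effect annotation: classify every tiled SNP against the gene
# models at codon level and tabulate categories by subgenome.

source("analysis/_common.R")

manifest <- read.delim(file.path(RESULTS, "manifest.tsv"))
genomes <- read_subgenomes(file.path(SIM_DIR, "subgenomes.fa"))
annotation <- read_gff3(file.path(SIM_DIR, "genes.gff3"))

eff <- classify_effect(manifest, annotation, genomes)
summary_tab <- summarize_annotation(eff, manifest$subgenome)
message("genomic position of the tiled SNPs (counts by subgenome):")
print(summary_tab)

write_tsv(eff, file.path(RESULTS, "effects.tsv"))
write_tsv(summary_tab, file.path(RESULTS, "effect_summary.tsv"))
message("wrote effects.tsv, effect_summary.tsv")
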