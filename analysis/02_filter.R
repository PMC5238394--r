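#!/usr/bin/env Rscript
# Step 2 — the filtering cascade: collapse duplicate records, remove
# homeologous SNPs (divergence between subgenomes masquerading as
# polymorphism), keep gene-proximal candidates, demand a unique probe
# context, and drop ambiguous/multiallelic loci. Reports the stage ledger
# and checks the discards against the simulation's truth labels.

source("analysis/_common.R")

genomes <- read_subgenomes(file.path(SIM_DIR, "subgenomes.fa"))
annotation <- read_gff3(file.path(SIM_DIR, "genes.gff3"))
cand <- read_candidates(file.path(SIM_DIR, "candidates.vcf"),
                        file.path(SIM_DIR, "candidates_flanks.tsv"))
# multi-ALT loci arrive as one expanded record per alternate allele, all
# flagged multiallelic; the cascade removes them at the ambiguity stage

filt <- run_filter_pipeline(cand, genomes, annotation,
                            window = STUDY_PARAMS$filter_window,
                            min_identity = STUDY_PARAMS$filter_identity,
                            min_aligned = STUDY_PARAMS$filter_min_aligned)
print(filt$ledger)

truth <- read_truth(file.path(SIM_DIR, "truth.json"))
oc <- merge(truth$labels, filt$outcomes, by = "snp_id")
message("truth label vs cascade outcome:")
print(table(oc$label, oc$outcome))

write_tsv(filt$passed, file.path(RESULTS, "passed_snps.tsv"))
jsonlite::write_json(unclass(filt$ledger), file.path(RESULTS, "ledger.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message(sprintf("%d of %d candidates passed; wrote passed_snps.tsv, ledger.json",
                filt$ledger$passed, filt$ledger$input))
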