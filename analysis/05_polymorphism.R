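#!/usr/bin/env Rscript
# Step 5 — genotype the reference panel on the manifest, QC the samples,
# partition polymorphism between wild (diploid) and cultivated (tetraploid)
# groups, and summarise per-SNP statistics and genome-wide density.

source("analysis/_common.R")

manifest <- read.delim(file.path(RESULTS, "manifest.tsv"))
panel <- generate_panel(manifest, STUDY_CONFIG)
write_genotypes(panel$panel, file.path(SIM_DIR, "genotypes.tsv"))

gm <- read_genotypes(file.path(SIM_DIR, "genotypes.tsv"), snps = manifest)
qc <- sample_qc(gm, min_call_rate = STUDY_PARAMS$qc_min_call_rate)
message(sprintf("sample QC: %d passed, %d failed (call rate <= %.2f)",
                nrow(qc$passed$calls), nrow(qc$failed),
                STUDY_PARAMS$qc_min_call_rate))

summ <- snp_summary(qc$passed)
message(sprintf(
  "means: major allele freq %.2f, heterozygosity %.2f, gene diversity %.2f, PIC %.2f",
  mean(summ$major_allele_freq, na.rm = TRUE),
  mean(summ$observed_heterozygosity, na.rm = TRUE),
  mean(summ$gene_diversity, na.rm = TRUE), mean(summ$pic, na.rm = TRUE)))

part <- polymorphic_partition(qc$passed, "ploidy")
message(sprintf(
  "polymorphic SNPs: %d in wild (diploid), %d in cultivated (tetraploid), %d common, %d combined",
  length(part$per_group$diploid), length(part$per_group$tetraploid),
  length(part$intersection), length(part$combined)))

genomes <- read_subgenomes(file.path(SIM_DIR, "subgenomes.fa"))
pm_lengths_mb <- vapply(c(genomes$A, genomes$B), nchar, numeric(1)) / 1e6
dens <- density_stats(table(manifest$pseudomolecule), pm_lengths_mb)

write_tsv(summ, file.path(RESULTS, "snp_summary.tsv"))
jsonlite::write_json(list(counts = as.list(part$counts),
                          density = dens$overall,
                          per_subgenome = dens$per_subgenome),
                     file.path(RESULTS, "polymorphism.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote genotypes.tsv, snp_summary.tsv, polymorphism.json")
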