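#!/usr/bin/env Rscript
# Step 3 — probe design: score both strands of every surviving SNP with the
# surrogate conversion score, classify recommendations, tile one strand per
# SNP, drop complement-symmetric ([A/T], [C/G]) markers, and select a
# genome-balanced array manifest.

source("analysis/_common.R")

passed <- read.delim(file.path(RESULTS, "passed_snps.tsv"))
cand <- read_candidates(file.path(SIM_DIR, "candidates.vcf"),
                        file.path(SIM_DIR, "candidates_flanks.tsv"))
genomes <- read_subgenomes(file.path(SIM_DIR, "subgenomes.fa"))

scored <- score_and_tile(passed, known_variants = cand)
eligible <- exclude_transversion_ambiguous(scored)
target <- floor(STUDY_PARAMS$design_target_fraction * nrow(eligible))
pm_lengths <- vapply(c(genomes$A, genomes$B), nchar, numeric(1))
manifest <- select_array(scored, target, pm_lengths)

message(sprintf("scored %d SNPs; %d eligible after [A/T]/[C/G] exclusion",
                nrow(scored), nrow(eligible)))
message("recommendation classes on the tiled strand:")
print(table(manifest$recommendation))

write_tsv(manifest, file.path(RESULTS, "manifest.tsv"))
report <- list(
  scored = nrow(scored), eligible = nrow(eligible), tiled = nrow(manifest),
  per_class = as.list(table(manifest$recommendation)),
  per_subgenome = as.list(table(manifest$subgenome)),
  per_pseudomolecule = as.list(table(manifest$pseudomolecule)))
jsonlite::write_json(report, file.path(RESULTS, "design_report.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message(sprintf("tiled %d SNPs onto the manifest; wrote manifest.tsv, design_report.json",
                nrow(manifest)))
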