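#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs: two diverged subgenome references with
# gene models, a candidate-SNP pool contaminated with homeolog-derived,
# duplicated-flank and multiallelic artifacts, and truth labels for every
# candidate. Everything downstream reads the files written here.

source("analysis/_common.R")

cfg <- STUDY_CONFIG
message(sprintf("simulating %d+%d pseudomolecules of %d bp at %.0f%% divergence",
                cfg$n_pseudomolecules_per_subgenome,
                cfg$n_pseudomolecules_per_subgenome,
                cfg$pseudomolecule_length, 100 * cfg$homeolog_divergence))
g <- generate_genomes(cfg)
cand <- generate_candidates(g$genomes, g$annotation, cfg)

write_fasta(cand$genomes, file.path(SIM_DIR, "subgenomes.fa"))
write_gff3(g$annotation, file.path(SIM_DIR, "genes.gff3"))
write_candidates(cand$candidates,
                 file.path(SIM_DIR, "candidates.vcf"),
                 file.path(SIM_DIR, "candidates_flanks.tsv"))
write_truth(cand$truth, file.path(SIM_DIR, "truth.json"))

message(sprintf("candidate pool: %d SNPs (%s)",
                nrow(cand$candidates),
                paste(names(table(cand$truth$labels$label)),
                      table(cand$truth$labels$label), collapse = ", ")))
message("wrote subgenomes.fa, genes.gff3, candidates.vcf(+flanks), truth.json")
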