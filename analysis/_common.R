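# Shared configuration for the analysis scripts. Each numbered script reads
# its inputs from results/ (written by earlier steps) so the whole workflow
# communicates through inspectable plain-text files.

library(allosnp)

RESULTS <- "results"
SIM_DIR <- file.path(RESULTS, "simulated")

STUDY_CONFIG <- sim_config(seed = 42)   # the emulated study conditions
STUDY_PARAMS <- run_config(seed = 42)

dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)

# read a combined FASTA back into the A/B subgenome structure
read_subgenomes <- function(path) {
  seqs <- read_fasta(path)
  list(A = seqs[startsWith(names(seqs), "A")],
       B = seqs[startsWith(names(seqs), "B")])
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "position"
  df[num] <- lapply(df[num], function(x) round(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
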