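# Shared fixtures and independent oracles. Everything is generated in code;
# the expensive small end-to-end run is computed once per session.

small_sim_config <- function(seed = 7, ...) {
  defaults <- list(
    n_pseudomolecules_per_subgenome = 4, pseudomolecule_length = 30000,
    n_genes = 24, n_true_snps = 200, n_homeolog_artifacts = 40,
    n_duplicated_flank_snps = 20, n_multiallelic = 10, n_trait_linked = 5,
    n_wild = 10, n_fastigiata = 12, n_hypogaea = 12, n_planted_specific = 15,
    n_sublineage_snps = 20, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixture_env <- new.env()

small_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- run_pipeline(small_sim_config(),
                                     run_config(log_level = "quiet"))
  }
  .fixture_env$run
}

expected_outcome <- c(true_variant = "passed",
                      homeolog_artifact = "homeologous",
                      duplicated_flank = "not_unique",
                      multiallelic = "ambiguous_multiallelic")

truth_outcomes <- function(run) {
  lab <- run$truth$labels
  data.frame(label = lab$label,
             outcome = run$filter$outcomes$outcome[
               match(lab$snp_id, run$filter$outcomes$snp_id)])
}

# Hand-size candidate row constructor for unit fixtures.
make_candidate <- function(snp_id, subgenome, pm, pos, ref, alt,
                           flank_left = strrep("A", 35),
                           flank_right = strrep("C", 35),
                           multiallelic = FALSE, trait_linked = FALSE) {
  data.frame(snp_id = snp_id, subgenome = subgenome, pseudomolecule = pm,
             position = pos, ref_allele = ref, alt_allele = alt,
             multiallelic = multiallelic, source_species = "A. hypogaea",
             flank_left = flank_left, flank_right = flank_right,
             trait_linked = trait_linked, stringsAsFactors = FALSE)
}

candidates_from_genome <- function(genomes, subgenome, pm, positions, alts) {
  s <- genomes[[subgenome]][[pm]]
  do.call(rbind, lapply(seq_along(positions), function(i) {
    p <- positions[i]
    make_candidate(sprintf("T%03d", i), subgenome, pm, p,
                   substr(s, p, p), alts[i],
                   flank_left = substr(s, p - 35, p - 1),
                   flank_right = substr(s, p + 1, p + 35))
  }))
}

# --- independent oracles -----------------------------------------------------

# Exhaustive sliding-window search implementing the qualifying-hit definition
# directly: every offset of both strands of both subgenomes.
oracle_placements <- function(context, genomes, min_identity = 0.94,
                              min_aligned = 60L) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") context else reverse_complement(context)
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    w <- length(qc)
    for (sub in c("A", "B")) {
      for (pm in names(genomes[[sub]])) {
        gc <- strsplit(genomes[[sub]][[pm]], "", fixed = TRUE)[[1]]
        L <- length(gc)
        for (s in seq((1L - w + min_aligned), L - min_aligned + 1L)) {
          gs <- max(1L, s); ge <- min(L, s + w - 1L)
          overlap <- ge - gs + 1L
          if (overlap < min_aligned) next
          eq <- qc[(gs - s + 1L):(ge - s + 1L)] == gc[gs:ge]
          identity <- mean(eq)
          r <- rle(eq)
          max_run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
          if (identity >= min_identity || max_run >= min_aligned) {
            out[[length(out) + 1L]] <- data.frame(
              sub = sub, pm = pm, start = s, strand = strand,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sub = character(), pm = character(), start = integer(),
               strand = character())
}

# Effect category by whole-transcript substitution and full translation,
# independent of the positional codon arithmetic in classify_effect().
oracle_effect <- function(pm, pos, ref, alt, annotation, genomes) {
  seqs <- c(genomes$A, genomes$B)
  gseq <- seqs[[pm]]
  mrna <- annotation[annotation$type == "mRNA" & annotation$seqid == pm, ]
  sev <- c(stop_gained = 1, stop_lost = 2, start_lost = 3,
           non_synonymous_start = 4, non_synonymous_stop = 5,
           non_synonymous_coding = 6, synonymous_coding = 7,
           UTR_5_prime = 8, UTR_3_prime = 9, intron = 10, intergenic = 11,
           others = 12)
  cats <- character(0)
  for (i in seq_len(nrow(mrna))) {
    if (pos < mrna$start[i] || pos > mrna$end[i]) next
    tid <- mrna$transcript_id[i]
    sub <- annotation[!is.na(annotation$transcript_id) &
                        annotation$transcript_id == tid, ]
    inb <- function(tp) {
      b <- sub[sub$type == tp, ]
      nrow(b) > 0 && any(pos >= b$start & pos <= b$end)
    }
    if (!inb("exon")) { cats <- c(cats, "intron"); next }
    if (inb("five_prime_UTR")) { cats <- c(cats, "UTR_5_prime"); next }
    if (inb("three_prime_UTR")) { cats <- c(cats, "UTR_3_prime"); next }
    if (!inb("CDS")) { cats <- c(cats, "others"); next }
    cds <- sub[sub$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    strand <- mrna$strand[i]
    get_cds <- function(genome_string) {
      segs <- vapply(seq_len(nrow(cds)), function(k)
        substr(genome_string, cds$start[k], cds$end[k]), character(1))
      s <- paste(segs, collapse = "")
      if (strand == "-") reverse_complement(s) else s
    }
    alt_genome <- gseq
    substr(alt_genome, pos, pos) <- alt
    ref_cds <- get_cds(gseq)
    alt_cds <- get_cds(alt_genome)
    if (nchar(ref_cds) %% 3 != 0) { cats <- c(cats, "others"); next }
    tr <- function(x) strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(x), if.fuzzy.codon = "X", no.init.codon = TRUE)),
      "", fixed = TRUE)[[1]]
    pa <- tr(ref_cds); pb <- tr(alt_cds)
    dif <- which(pa != pb)
    if (!length(dif)) { cats <- c(cats, "synonymous_coding"); next }
    d <- dif[1]
    n_aa <- length(pa)
    cat <- if (pb[d] == "*") "stop_gained"
      else if (pa[d] == "*" && d == n_aa) "stop_lost"
      else if (d == 1) "start_lost"
      else if (d == 2) "non_synonymous_start"
      else if (d == n_aa - 1) "non_synonymous_stop"
      else "non_synonymous_coding"
    cats <- c(cats, cat)
  }
  if (!length(cats)) return("intergenic")
  cats[which.min(sev[cats])]
}

oracle_distance <- function(calls) {
  n <- nrow(calls)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- calls[i, ] != -1L & calls[j, ] != -1L
    D[i, j] <- if (any(ok)) mean(abs(calls[i, ok] - calls[j, ok]) / 2) else NA
  }
  dimnames(D) <- list(rownames(calls), rownames(calls))
  D
}

oracle_pic <- function(p) {
  # direct double sum over allele pairs
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
  }
  s
}

random_genotype_matrix <- function(n = 8, m = 30, missing = 0.1) {
  calls <- matrix(sample(c(-1L, 0L, 1L, 2L), n * m, replace = TRUE,
                         prob = c(missing, (1 - missing) * c(0.5, 0.2, 0.3))),
                  nrow = n)
  rownames(calls) <- sprintf("S%02d", seq_len(n))
  colnames(calls) <- sprintf("SNP%03d", seq_len(m))
  samples <- data.frame(sample = rownames(calls),
                        species = "A. hypogaea",
                        ploidy = rep(c("diploid", "tetraploid"), length.out = n),
                        category = rep(c("wild", "fastigiata", "hypogaea"),
                                       length.out = n),
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, data.frame(snp_id = colnames(calls)))
}
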