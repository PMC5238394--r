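#' Filter-ledger accounting for the candidate-SNP cascade
#'
#' A ledger records how many candidates entered the cascade and how many left
#' at each stage: `discarded_identical` (byte-identical duplicate records),
#' `discarded_both_genomes` (homeologous SNPs — the apparent polymorphism is
#' fixed subgenome divergence), `discarded_both_strands` (probe context has
#' additional qualifying genomic placements in either orientation, i.e. the
#' non-uniqueness discard), `discarded_far_from_gene`,
#' `discarded_flank_unevaluable`, `discarded_self_match_failed`, and
#' `discarded_ambiguous_multiallelic`. If `passed` is omitted it is computed
#' by subtraction; conservation (input = passed + all discards) is enforced.
#'
#' @param input candidates entering the cascade.
#' @param discarded_identical,discarded_both_genomes,discarded_both_strands
#'   stage discard counts.
#' @param discarded_far_from_gene,discarded_flank_unevaluable,discarded_self_match_failed,discarded_ambiguous_multiallelic
#'   further stage discard counts.
#' @param passed survivors; computed by subtraction when `NULL`.
#' @return a `filter_ledger` object (named list of counts).
#' @export
filter_ledger <- function(input,
                          discarded_identical = 0,
                          discarded_both_genomes = 0,
                          discarded_both_strands = 0,
                          discarded_far_from_gene = 0,
                          discarded_flank_unevaluable = 0,
                          discarded_self_match_failed = 0,
                          discarded_ambiguous_multiallelic = 0,
                          passed = NULL) {
  counts <- c(input = input,
              discarded_identical = discarded_identical,
              discarded_both_genomes = discarded_both_genomes,
              discarded_both_strands = discarded_both_strands,
              discarded_far_from_gene = discarded_far_from_gene,
              discarded_flank_unevaluable = discarded_flank_unevaluable,
              discarded_self_match_failed = discarded_self_match_failed,
              discarded_ambiguous_multiallelic = discarded_ambiguous_multiallelic)
  if (any(counts < 0)) stop("ledger counts must be >= 0")
  discarded <- sum(counts[-1])
  if (is.null(passed)) passed <- input - discarded
  if (passed < 0 || input != passed + discarded)
    stop("ledger conservation violated: input != passed + sum(discarded)")
  out <- as.list(c(counts, passed = passed))
  class(out) <- "filter_ledger"
  out
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("Candidate-SNP filter ledger\n")
  for (n in names(x)) cat(sprintf("  %-34s %d\n", n, x[[n]]))
  invisible(x)
}

#' Collapse byte-identical candidate records
#'
#' Candidates identical in (subgenome, pseudomolecule, position, ref, alt)
#' collapse to one record; the first occurrence is kept. Records at the same
#' locus with different alternate alleles are both kept (handled later by the
#' multiallelic filter).
#'
#' @param candidates candidate data frame.
#' @return list with `kept` and `n_removed`.
#' @export
dedupe_identical <- function(candidates) {
  key <- paste(candidates$subgenome, candidates$pseudomolecule,
               candidates$position, candidates$ref_allele,
               candidates$alt_allele, sep = "\r")
  dup <- duplicated(key)
  list(kept = candidates[!dup, , drop = FALSE], n_removed = sum(dup))
}

#' Flag homeologous SNP candidates
#'
#' A candidate is homeologous when its 71-base probe context aligns to the
#' other subgenome at >= `min_identity` over the full overlap AND the aligned
#' base at the SNP column equals the candidate's alternate allele: the
#' apparent polymorphism is explained by fixed subgenome divergence, not by
#' variation among accessions. Candidates whose flanks are shorter than 35
#' bases (pseudomolecule edge) cannot be evaluated and are reported
#' separately.
#'
#' @param candidates candidate data frame.
#' @param genomes list with subgenome references `A` and `B`.
#' @param index optional prebuilt [build_genome_index()].
#' @param min_identity cross-alignment identity threshold (default 0.94).
#' @return list with logical vectors `flagged` and `unevaluable` aligned to
#'   `candidates` rows.
#' @export
flag_homeologous <- function(candidates, genomes, index = NULL,
                             min_identity = 0.94) {
  if (is.null(index)) index <- build_genome_index(genomes)
  n <- nrow(candidates)
  unevaluable <- nchar(candidates$flank_left) != 35L |
    nchar(candidates$flank_right) != 35L
  flagged <- logical(n)
  eval_idx <- which(!unevaluable)
  if (length(eval_idx)) {
    ctx <- probe_context(candidates[eval_idx, , drop = FALSE])
    pl <- find_placements(ctx, index, min_identity = min_identity,
                          min_aligned = 71L)  # identity branch only
    for (k in seq_along(eval_idx)) {
      i <- eval_idx[k]
      other <- if (candidates$subgenome[i] == "A") "B" else "A"
      hits <- pl[pl$qid == k & pl$sub == other & pl$identity >= min_identity, ]
      if (!nrow(hits)) next
      alts <- strsplit(candidates$alt_allele[i], ",", fixed = TRUE)[[1]]
      flagged[i] <- any(hits$snp_base %in% alts, na.rm = TRUE)
    }
  }
  list(flagged = flagged, unevaluable = unevaluable)
}

#' Keep candidates within a window of annotated genes
#'
#' Keeps candidates whose position lies within `window` bases of any gene
#' span (distance 0 inside a gene), strand-agnostic; the window boundary is
#' inclusive. Candidates on pseudomolecules absent from the annotation are
#' dropped with a warning and counted separately.
#'
#' @param candidates candidate data frame.
#' @param annotation feature data frame (uses `type == "gene"` rows).
#' @param window distance in bases (default 10000).
#' @return list with `kept`, `n_removed` (outside the window) and
#'   `n_unplaced` (pseudomolecule missing from the annotation).
#' @export
filter_near_genes <- function(candidates, annotation, window = 10000) {
  genes <- annotation[annotation$type == "gene", , drop = FALSE]
  keep <- logical(nrow(candidates))
  unplaced <- logical(nrow(candidates))
  for (p in unique(candidates$pseudomolecule)) {
    idx <- which(candidates$pseudomolecule == p)
    g <- genes[genes$seqid == p, , drop = FALSE]
    if (!nrow(g)) {
      unplaced[idx] <- TRUE
      next
    }
    for (i in idx) {
      pos <- candidates$position[i]
      keep[i] <- any(pos >= g$start - window & pos <= g$end + window)
    }
  }
  if (any(unplaced))
    warning(sprintf("%d candidates on pseudomolecules absent from the annotation were dropped",
                    sum(unplaced)))
  list(kept = candidates[keep, , drop = FALSE],
       n_removed = sum(!keep & !unplaced), n_unplaced = sum(unplaced))
}

#' Probe-context uniqueness against both subgenomes
#'
#' Searches each candidate's 71-base context against both subgenomes in both
#' orientations and counts qualifying placements (full-overlap identity >=
#' `min_identity`, or a contiguous exact-match run >= `min_aligned` bases).
#' The placement at the candidate's own locus is the required self-match; in
#' an allotetraploid one placement on the other subgenome is the expected
#' homeologous counterpart (adjudicated by the dedicated homeolog filter) and
#' is not counted as a duplicate — every further qualifying placement is.
#'
#' @param candidates candidate data frame.
#' @param genomes list with subgenome references `A` and `B`.
#' @param index optional prebuilt [build_genome_index()].
#' @param min_identity full-overlap identity threshold (default 0.94).
#' @param min_aligned exact-run / minimum-overlap length (default 60).
#' @return data frame with `snp_id`, `is_unique`, `duplicate_count`,
#'   `self_found`.
#' @export
uniqueness_check <- function(candidates, genomes, index = NULL,
                             min_identity = 0.94, min_aligned = 60L) {
  if (is.null(index)) index <- build_genome_index(genomes)
  ctx <- probe_context(candidates)
  pl <- find_placements(ctx, index, min_identity = min_identity,
                        min_aligned = min_aligned)
  n <- nrow(candidates)
  res <- data.frame(snp_id = candidates$snp_id,
                    is_unique = logical(n),
                    duplicate_count = integer(n),
                    self_found = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hits <- pl[pl$qid == i, ]
    own <- candidates$subgenome[i]
    self_start <- candidates$position[i] - 35L
    is_self <- hits$sub == own & hits$pm == candidates$pseudomolecule[i] &
      hits$strand == "+" & hits$start == self_start
    same_extra <- sum(hits$sub == own & !is_self)
    other_n <- sum(hits$sub != own)
    dup <- same_extra + max(0L, other_n - 1L)
    res$self_found[i] <- any(is_self)
    res$duplicate_count[i] <- dup
    res$is_unique[i] <- any(is_self) && dup == 0L
  }
  res
}

#' Remove ambiguous and multiallelic candidates
#'
#' Removes candidates flagged multiallelic (more than one alternate allele),
#' candidates at loci observed with more than two distinct alleles across the
#' table, and candidates whose ref or alt symbols are not plain A/C/G/T.
#'
#' @param candidates candidate data frame.
#' @return list with `kept` and `n_removed`.
#' @export
remove_ambiguous_multiallelic <- function(candidates) {
  n <- nrow(candidates)
  if (!n) return(list(kept = candidates, n_removed = 0L))
  multi <- if ("multiallelic" %in% names(candidates))
    candidates$multiallelic else rep(FALSE, n)
  multi <- multi | grepl(",", candidates$alt_allele, fixed = TRUE)
  bad_base <- !(candidates$ref_allele %in% DNA_BASES) |
    !vapply(strsplit(candidates$alt_allele, ",", fixed = TRUE),
            function(a) all(a %in% DNA_BASES), logical(1))
  locus <- paste(candidates$subgenome, candidates$pseudomolecule,
                 candidates$position, sep = "\r")
  alleles_per_locus <- tapply(
    paste(candidates$ref_allele, candidates$alt_allele, sep = ","), locus,
    function(a) length(unique(unlist(strsplit(a, ",", fixed = TRUE)))))
  over <- names(alleles_per_locus)[alleles_per_locus > 2]
  remove <- multi | bad_base | locus %in% over
  list(kept = candidates[!remove, , drop = FALSE], n_removed = sum(remove))
}

#' Run the full candidate-SNP filtering cascade
#'
#' Applies, in order: duplicate-record collapse, homeolog removal, gene
#' proximity, probe-context uniqueness, and ambiguity/multiallelic removal.
#' Returns the survivors (with `duplicate_count` attached for probe design)
#' and a conservation-checked [filter_ledger()].
#'
#' @param candidates candidate data frame.
#' @param genomes list with subgenome references `A` and `B`.
#' @param annotation feature data frame.
#' @param window gene-proximity window in bases (default 10000).
#' @param min_identity qualifying-hit identity threshold (default 0.94).
#' @param min_aligned qualifying-hit aligned-length threshold (default 60).
#' @param index optional prebuilt [build_genome_index()].
#' @return list with `passed` (data frame), `ledger`, and `outcomes` (one row
#'   per input candidate: `snp_id`, `outcome`).
#' @export
run_filter_pipeline <- function(candidates, genomes, annotation,
                                window = 10000, min_identity = 0.94,
                                min_aligned = 60L, index = NULL) {
  input <- nrow(candidates)
  if (!input) {
    return(list(passed = candidates, ledger = filter_ledger(0),
                outcomes = data.frame(snp_id = character(),
                                      outcome = character())))
  }
  if (is.null(index)) index <- build_genome_index(genomes)
  outcome <- setNames(rep(NA_character_, input), candidates$snp_id)
  mark <- function(ids, what) outcome[ids] <<- what

  dd <- dedupe_identical(candidates)
  mark(setdiff(candidates$snp_id, dd$kept$snp_id), "identical")
  cur <- dd$kept

  hf <- flag_homeologous(cur, genomes, index = index,
                         min_identity = min_identity)
  n_homeo <- sum(hf$flagged & !hf$unevaluable)
  n_uneval <- sum(hf$unevaluable)
  mark(cur$snp_id[hf$flagged & !hf$unevaluable], "homeologous")
  mark(cur$snp_id[hf$unevaluable], "flank_unevaluable")
  cur <- cur[!hf$flagged & !hf$unevaluable, , drop = FALSE]

  before <- cur$snp_id
  ng <- filter_near_genes(cur, annotation, window = window)
  mark(setdiff(before, ng$kept$snp_id), "far_from_gene")
  cur <- ng$kept

  uq <- uniqueness_check(cur, genomes, index = index,
                         min_identity = min_identity,
                         min_aligned = min_aligned)
  n_self_fail <- sum(!uq$self_found)
  n_dup <- sum(uq$self_found & !uq$is_unique)
  mark(cur$snp_id[!uq$self_found], "self_match_failed")
  mark(cur$snp_id[uq$self_found & !uq$is_unique], "not_unique")
  cur$duplicate_count <- uq$duplicate_count
  cur <- cur[uq$is_unique, , drop = FALSE]

  am <- remove_ambiguous_multiallelic(cur)
  mark(setdiff(cur$snp_id, am$kept$snp_id), "ambiguous_multiallelic")
  cur <- am$kept
  mark(cur$snp_id, "passed")

  ledger <- filter_ledger(
    input = input,
    discarded_identical = dd$n_removed,
    discarded_both_genomes = n_homeo,
    discarded_both_strands = n_dup,
    discarded_far_from_gene = ng$n_removed + ng$n_unplaced,
    discarded_flank_unevaluable = n_uneval,
    discarded_self_match_failed = n_self_fail,
    discarded_ambiguous_multiallelic = am$n_removed)
  if (!nrow(cur)) warning("no candidates survived the filtering cascade")
  list(passed = cur, ledger = ledger,
       outcomes = data.frame(snp_id = candidates$snp_id,
                             outcome = unname(outcome[candidates$snp_id]),
                             stringsAsFactors = FALSE))
}
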