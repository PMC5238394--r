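#' Construct a genotype matrix
#'
#' Samples-by-SNPs call matrix with per-sample metadata. Calls are coded
#' 0 = ref-homozygous, 1 = heterozygous, 2 = alt-homozygous, -1 = missing
#' (the diploidized cluster calls an array reports, taken at face value for
#' tetraploids).
#'
#' @param calls integer matrix (samples x snps) with codes in {-1,0,1,2};
#'   rownames are sample ids, colnames snp ids.
#' @param samples data frame with columns `sample`, `species`, `ploidy`,
#'   `category`; row order must match `calls`.
#' @param snps data frame of SNP records (at least `snp_id`), matching the
#'   columns of `calls`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, snps) {
  if (!all(calls %in% c(-1L, 0L, 1L, 2L)))
    stop("genotype calls must be coded -1, 0, 1 or 2")
  if (nrow(calls) != nrow(samples))
    stop("calls and sample metadata disagree on sample count")
  if (ncol(calls) != nrow(snps))
    stop("calls and snp table disagree on SNP count")
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp ids")
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  print(table(x$samples$category))
  invisible(x)
}

subset_gm <- function(gm, sample_idx = NULL, snp_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(nrow(gm$calls))
  if (is.null(snp_idx)) snp_idx <- seq_len(ncol(gm$calls))
  genotype_matrix(gm$calls[sample_idx, snp_idx, drop = FALSE],
                  gm$samples[sample_idx, , drop = FALSE],
                  gm$snps[snp_idx, , drop = FALSE])
}

#' Per-sample quality control
#'
#' Removes samples whose call rate is not strictly above `min_call_rate`.
#' DQC — an intensity-level metric that cannot be derived from genotype
#' calls — is thresholded only when supplied as a `dqc` column in the sample
#' metadata.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call_rate samples must exceed this call rate (default 0.90,
#'   strict inequality).
#' @param min_dqc samples must exceed this DQC when a `dqc` column exists
#'   (default 0.75).
#' @return list with `passed` (genotype_matrix) and `failed` (per-sample
#'   report data frame).
#' @export
sample_qc <- function(gm, min_call_rate = 0.90, min_dqc = 0.75) {
  cr <- rowMeans(gm$calls != -1L)
  ok <- cr > min_call_rate
  if (!is.null(gm$samples$dqc)) ok <- ok & gm$samples$dqc > min_dqc
  report <- data.frame(sample = gm$samples$sample, call_rate = cr,
                       passed = ok, stringsAsFactors = FALSE)
  if (!any(ok)) {
    print(report)
    stop("all samples failed QC")
  }
  list(passed = subset_gm(gm, sample_idx = which(ok)),
       failed = report[!ok, , drop = FALSE])
}

#' Per-SNP summary statistics
#'
#' Allele frequencies count each heterozygote as half an allele over the
#' non-missing calls. Reports call rate, major/minor allele frequency,
#' observed heterozygosity, gene diversity (expected heterozygosity,
#' \eqn{1 - \sum p_i^2}) and Botstein's polymorphism information content,
#' \eqn{PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}. A SNP is
#' polymorphic when at least two distinct non-missing call codes occur.
#' SNPs with zero non-missing calls get call rate 0 and NA statistics.
#'
#' @param gm a [genotype_matrix()].
#' @return data frame, one row per SNP.
#' @export
snp_summary <- function(gm) {
  calls <- gm$calls
  nonmiss <- calls != -1L
  n_obs <- colSums(nonmiss)
  n_het <- colSums(calls == 1L)
  n_alt2 <- colSums(calls == 2L)
  p_alt <- ifelse(n_obs > 0, (n_het + 2 * n_alt2) / (2 * n_obs), NA_real_)
  maj <- pmax(p_alt, 1 - p_alt)
  minf <- pmin(p_alt, 1 - p_alt)
  het_obs <- ifelse(n_obs > 0, n_het / n_obs, NA_real_)
  gd <- 1 - (p_alt^2 + (1 - p_alt)^2)
  pic <- gd - 2 * p_alt^2 * (1 - p_alt)^2
  poly <- vapply(seq_len(ncol(calls)), function(j) {
    length(unique(calls[nonmiss[, j], j])) >= 2L
  }, logical(1))
  data.frame(snp_id = gm$snps$snp_id,
             call_rate = n_obs / nrow(calls),
             n_obs = n_obs,
             major_allele_freq = maj,
             minor_allele_freq = minf,
             observed_heterozygosity = het_obs,
             gene_diversity = gd,
             pic = pic,
             polymorphic = poly,
             stringsAsFactors = FALSE)
}

#' Botstein PIC for an allele-frequency vector
#'
#' @param p allele frequencies summing to 1.
#' @return \eqn{1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}.
#' @export
pic_from_frequencies <- function(p) {
  s2 <- sum(p^2)
  cross <- 0
  k <- length(p)
  if (k > 1) {
    for (i in seq_len(k - 1))
      cross <- cross + sum(2 * p[i]^2 * p[(i + 1):k]^2)
  }
  1 - s2 - cross
}

#' Partition polymorphic SNPs by sample group
#'
#' A SNP is polymorphic within a group when at least two distinct non-missing
#' call codes occur among that group's samples. Returns the per-group
#' polymorphic SNP sets, their intersection, and the combined set (SNPs
#' polymorphic across the whole panel analysed jointly).
#'
#' @param gm a [genotype_matrix()].
#' @param groups named character vector (names = sample ids) or a metadata
#'   column name (e.g. `"ploidy"`).
#' @return list with `per_group` (list of snp_id vectors), `intersection`,
#'   `combined`, and `counts`.
#' @export
polymorphic_partition <- function(gm, groups = "ploidy") {
  if (is.character(groups) && length(groups) == 1) {
    if (!groups %in% names(gm$samples))
      stop(sprintf("unknown group label '%s'", groups))
    groups <- setNames(gm$samples[[groups]], gm$samples$sample)
  }
  groups <- groups[gm$samples$sample]
  if (any(is.na(groups))) stop("every sample needs a group label")
  poly_in <- function(rows) {
    calls <- gm$calls[rows, , drop = FALSE]
    vapply(seq_len(ncol(calls)), function(j) {
      v <- calls[, j]; v <- v[v != -1L]
      length(unique(v)) >= 2L
    }, logical(1))
  }
  per_group <- lapply(split(seq_along(groups), groups), function(rows) {
    gm$snps$snp_id[poly_in(rows)]
  })
  combined <- gm$snps$snp_id[poly_in(seq_along(groups))]
  inter <- Reduce(intersect, per_group)
  list(per_group = per_group, intersection = inter, combined = combined,
       counts = c(vapply(per_group, length, integer(1)),
                  intersection = length(inter), combined = length(combined)))
}

#' Percent-polymorphism report over marker groups
#'
#' Standard reporting arithmetic for a table of marker groups (e.g. source
#' species): percent polymorphic to one decimal, a total row, and each
#' group's share of the polymorphic markers.
#'
#' @param groups data frame with columns `group`, `n_total`,
#'   `n_polymorphic`.
#' @return data frame with `pct_polymorphic` and `share_of_polymorphic`
#'   added and a `Total` row appended.
#' @export
polymorphism_report <- function(groups) {
  stopifnot(all(c("group", "n_total", "n_polymorphic") %in% names(groups)))
  if (any(groups$n_polymorphic > groups$n_total))
    stop("n_polymorphic cannot exceed n_total")
  out <- groups[, c("group", "n_total", "n_polymorphic")]
  out <- rbind(out, data.frame(group = "Total",
                               n_total = sum(out$n_total),
                               n_polymorphic = sum(out$n_polymorphic)))
  out$pct_polymorphic <- round(100 * out$n_polymorphic / out$n_total, 1)
  tot <- sum(groups$n_polymorphic)
  out$share_of_polymorphic <-
    round(100 * out$n_polymorphic / tot, 1)
  out
}

#' SNP density summaries per pseudomolecule and subgenome
#'
#' Recomputes the standard density bookkeeping from per-pseudomolecule SNP
#' counts and pseudomolecule lengths: SNPs per Mb (2 decimals),
#' mean SNPs per pseudomolecule (nearest integer), and Kb per SNP
#' (total length in Kb / SNP count, nearest integer). Subgenome membership
#' is the leading letter of the pseudomolecule name.
#'
#' @param counts named integer vector of SNP counts per pseudomolecule.
#' @param lengths_mb named numeric vector of pseudomolecule lengths in Mb
#'   (same names).
#' @return list with `per_pseudomolecule` (data frame) and `per_subgenome` /
#'   `overall` summaries.
#' @export
density_stats <- function(counts, lengths_mb) {
  if (any(lengths_mb <= 0)) stop("pseudomolecule lengths must be > 0")
  pms <- names(lengths_mb)
  counts <- counts[pms]
  counts[is.na(counts)] <- 0L
  per_pm <- data.frame(
    pseudomolecule = pms,
    n_snps = as.integer(counts),
    length_mb = as.numeric(lengths_mb),
    snps_per_mb = round(counts / lengths_mb, 2),
    stringsAsFactors = FALSE)
  sub <- substr(pms, 1, 1)
  round_half_up <- function(x) floor(x + 0.5)  # reporting convention
  summarize <- function(idx) {
    n <- sum(counts[idx])
    len_mb <- sum(lengths_mb[idx])
    list(n_snps = as.integer(n),
         length_mb = len_mb,
         mean_per_pseudomolecule = round_half_up(n / length(idx)),
         snps_per_mb = round(n / len_mb, 2),
         kb_per_snp = if (n == 0) NA_real_ else round_half_up(len_mb * 1000 / n))
  }
  per_sub <- lapply(split(seq_along(pms), sub), summarize)
  overall <- summarize(seq_along(pms))
  list(per_pseudomolecule = per_pm, per_subgenome = per_sub,
       overall = overall)
}
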