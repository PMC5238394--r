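#' Allele-sharing distance between samples
#'
#' For samples a and b, \eqn{d(a,b)} is the mean over SNPs non-missing in
#' both of \eqn{|g_a - g_b| / 2}, with dosages in {0,1,2}; identical samples
#' are at 0, opposite homozygotes across all SNPs at 1. Computed via
#' indicator cross-products so large panels stay fast.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric numeric matrix with zero diagonal; a pair with no SNP
#'   non-missing in both gets NA.
#' @export
allele_sharing_distance <- function(gm) {
  calls <- gm$calls
  if (nrow(calls) < 2) stop("need at least 2 samples")
  I0 <- (calls == 0L) * 1
  I1 <- (calls == 1L) * 1
  I2 <- (calls == 2L) * 1
  V <- (calls != -1L) * 1
  Aij <- I0 %*% t(I1) + 2 * (I0 %*% t(I2)) + I1 %*% t(I2)
  S <- Aij + t(Aij)
  N <- V %*% t(V)
  D <- ifelse(N > 0, S / (2 * N), NA_real_)
  diag(D) <- 0
  dimnames(D) <- list(gm$samples$sample, gm$samples$sample)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-matrix minimisation with the usual
#' branch-length assignment); on an additive distance matrix the tree's path
#' lengths reproduce the input distances.
#'
#' @param dist_matrix complete symmetric matrix from
#'   [allele_sharing_distance()] (or any distance matrix).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dist_matrix) {
  if (any(is.na(dist_matrix)))
    stop("distance matrix is incomplete (sample pairs with no shared calls)")
  if (nrow(dist_matrix) < 3) stop("neighbor joining needs at least 3 samples")
  ape::nj(stats::as.dist(dist_matrix))
}

#' Cut a tree into k clusters
#'
#' Removes internal edges longest-first (ties broken by the tree's postorder
#' edge index, terminal edges considered after all internal ones) until the
#' leaves fall into k connected components; cuts that would only split off a
#' leafless subtree are skipped. Cluster ids are numbered by first
#' appearance in tip order.
#'
#' @param tree a `phylo` tree.
#' @param k number of clusters, 2 <= k <= number of leaves.
#' @return named integer vector: leaf -> cluster id.
#' @export
assign_clusters <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  if (k < 2 || k > n_tip) stop("k must be between 2 and the number of leaves")
  tr <- ape::reorder.phylo(tree, "postorder")
  e <- tr$edge
  len <- tr$edge.length
  n_node <- max(e)
  internal <- e[, 2] > n_tip
  pri <- order(!internal, -len, seq_along(len))  # internal first, long first

  leaf_components <- function(cut_set) {
    parent <- seq_len(n_node)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (i in seq_len(nrow(e))) {
      if (cut_set[i]) next
      a <- find(e[i, 1]); b <- find(e[i, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n_tip), find, integer(1))
  }

  cut_set <- logical(nrow(e))
  comp <- leaf_components(cut_set)
  for (i in pri) {
    if (length(unique(comp)) >= k) break
    cut_set[i] <- TRUE
    new_comp <- leaf_components(cut_set)
    if (length(unique(new_comp)) > length(unique(comp))) {
      comp <- new_comp  # the cut separates leaves; keep it
    } else {
      cut_set[i] <- FALSE
    }
  }
  ids <- match(comp, unique(comp))
  setNames(ids, tr$tip.label)
}

#' Alternate-allele frequencies per sample category
#'
#' Frequencies are computed from non-missing calls with heterozygotes
#' counting half an allele.
#'
#' @param gm a [genotype_matrix()] whose sample metadata has a `category`
#'   column (fastigiata / hypogaea / wild).
#' @return data frame with, per category, `freq_<category>` and
#'   `n_<category>` (non-missing call count).
#' @export
category_frequencies <- function(gm) {
  cats <- unique(gm$samples$category)
  out <- data.frame(snp_id = gm$snps$snp_id, stringsAsFactors = FALSE)
  for (cat in cats) {
    rows <- which(gm$samples$category == cat)
    if (!length(rows)) stop(sprintf("empty category '%s'", cat))
    calls <- gm$calls[rows, , drop = FALSE]
    nonmiss <- calls != -1L
    n_obs <- colSums(nonmiss)
    alt <- colSums(calls == 1L) + 2 * colSums(calls == 2L)
    out[[paste0("freq_", cat)]] <-
      ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
    out[[paste0("n_", cat)]] <- n_obs
  }
  out
}

#' Scan for subspecies-specific high-frequency SNPs
#'
#' A SNP is specific to one cultivated category when its alternate-allele
#' frequency is strictly above `threshold` there and at most
#' `1 - threshold` in the other cultivated category (the operational reading
#' of "contrasting frequencies"). A specific SNP is additionally
#' shared-with-wild when the wild frequency is also above `threshold`.
#' Counts are reported both ways: with the wild-shared SNPs inside their
#' cultivated class, and broken out separately.
#'
#' @param freqs output of [category_frequencies()] (needs
#'   `freq_fastigiata`, `freq_hypogaea`, `freq_wild`).
#' @param threshold frequency threshold (default 0.80, strict >).
#' @param snps optional SNP table with `snp_id` and `pseudomolecule` for
#'   per-pseudomolecule counts.
#' @return list with `snps` (classified data frame) and `counts`.
#' @export
specific_high_frequency_scan <- function(freqs, threshold = 0.80,
                                         snps = NULL) {
  ff <- freqs$freq_fastigiata
  fh <- freqs$freq_hypogaea
  fw <- freqs$freq_wild
  fast <- !is.na(ff) & !is.na(fh) & ff > threshold & fh <= 1 - threshold
  hypo <- !is.na(ff) & !is.na(fh) & fh > threshold & ff <= 1 - threshold
  cls <- ifelse(fast, "fastigiata_specific",
                ifelse(hypo, "hypogaea_specific", "none"))
  shared <- cls != "none" & !is.na(fw) & fw > threshold
  out <- data.frame(snp_id = freqs$snp_id, class = cls,
                    shared_with_wild = shared, stringsAsFactors = FALSE)
  counts <- list(
    total_specific = sum(cls != "none"),
    fastigiata_specific = sum(cls == "fastigiata_specific"),
    hypogaea_specific = sum(cls == "hypogaea_specific"),
    fastigiata_shared_with_wild = sum(shared & cls == "fastigiata_specific"),
    hypogaea_shared_with_wild = sum(shared & cls == "hypogaea_specific"),
    hypogaea_specific_not_shared = sum(!shared & cls == "hypogaea_specific"),
    fastigiata_specific_not_shared = sum(!shared & cls == "fastigiata_specific"))
  if (!is.null(snps)) {
    pm <- snps$pseudomolecule[match(out$snp_id, snps$snp_id)]
    counts$per_pseudomolecule <-
      table(pm[out$class != "none"], out$class[out$class != "none"])
  }
  list(snps = out, counts = counts)
}

#' Restrict scanned SNPs to moderate and high predicted effects
#'
#' Keeps classified (specific) SNPs whose effect category is missense
#' (`non_synonymous_coding`, moderate) or nonsense-like (`stop_gained`,
#' `stop_lost`, `start_lost`, high), and returns the distinct genes hit.
#'
#' @param scan_result `snps` element of [specific_high_frequency_scan()].
#' @param annotations output of [classify_effect()].
#' @return list with `snps` (with `effect_class` and `gene_id`) and `genes`.
#' @export
scan_effect_filter <- function(scan_result, annotations) {
  specific <- scan_result[scan_result$class != "none", , drop = FALSE]
  ann <- annotations[match(specific$snp_id, annotations$snp_id), , drop = FALSE]
  moderate <- ann$category == "non_synonymous_coding"
  high <- ann$category %in% c("stop_gained", "stop_lost", "start_lost")
  keep <- which(moderate | high)
  out <- specific[keep, , drop = FALSE]
  out$effect_class <- ifelse(high[keep], "high", "moderate")
  out$category <- ann$category[keep]
  out$gene_id <- ann$gene_id[keep]
  list(snps = out, genes = sort(unique(out$gene_id)))
}
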