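#' Surrogate probe conversion score
#'
#' The array vendor's conversion probability ("p-convert") comes from a
#' proprietary random-forest model over probe sequence, binding energy and
#' expected non-specific hybridization. This package replaces it with a
#' documented deterministic surrogate so the downstream recommendation and
#' tiling logic can be exercised faithfully:
#'
#' \deqn{p = clamp(0.95 - |GC - 0.45| - 0.25\,min(dup, 2) - 0.12\,wobble -
#'   0.10\,poly,\ 0,\ 1)}
#'
#' where GC is the 71-base context GC fraction. The score is monotonically
#' non-increasing in every penalty term.
#'
#' @param context 71-base probe context (vectorised).
#' @param duplicate_count extra qualifying genomic placements.
#' @param wobble_count interfering known variants within the context.
#' @param poly_count homopolymer runs of length >= 6 within the context.
#' @return numeric p-convert in [0,1].
#' @export
score_probe <- function(context, duplicate_count = 0, wobble_count = 0,
                        poly_count = 0) {
  if (any(nchar(context) != 71L))
    stop("probe context must be exactly 71 bases")
  gc <- gc_fraction(context)
  p <- 0.95 - 1.0 * abs(gc - 0.45) - 0.25 * pmin(duplicate_count, 2) -
    0.12 * wobble_count - 0.10 * poly_count
  pmin(pmax(p, 0), 1)
}

#' Count homopolymer runs of a minimum length
#'
#' @param context probe context string(s).
#' @param min_len minimum run length (default 6).
#' @return integer count per context.
#' @export
count_homopolymer_runs <- function(context, min_len = 6L) {
  vapply(context, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    sum(r$lengths >= min_len)
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify a probe's recommendation
#'
#' The exclusion rules take precedence: a probe is `not_recommended` when it
#' has any duplicate placement, any homopolymer run, p-convert below 0.4, a
#' wobble closer than 21 bases to the target SNP, or three or more wobbles.
#' Otherwise it is `recommended` when p-convert exceeds 0.6 with no wobbles
#' and no homopolymer runs, and `neutral` in all remaining cases.
#'
#' @param p_convert conversion score in [0,1].
#' @param duplicate_count,poly_count,wobble_count,wobble_distance probe
#'   metrics; `wobble_distance` is bases from the target SNP to the nearest
#'   other known variant in the context (`Inf` when there is none).
#' @return character vector: "recommended", "neutral" or "not_recommended".
#' @export
classify_recommendation <- function(p_convert, duplicate_count = 0,
                                    poly_count = 0, wobble_count = 0,
                                    wobble_distance = Inf) {
  n <- max(length(p_convert), length(duplicate_count), length(poly_count),
           length(wobble_count), length(wobble_distance))
  p_convert <- rep_len(p_convert, n)
  duplicate_count <- rep_len(duplicate_count, n)
  poly_count <- rep_len(poly_count, n)
  wobble_count <- rep_len(wobble_count, n)
  wobble_distance <- rep_len(wobble_distance, n)
  not_rec <- duplicate_count > 0 | poly_count > 0 | p_convert < 0.4 |
    wobble_distance < 21 | wobble_count >= 3
  rec <- p_convert > 0.6 & wobble_count == 0 & poly_count == 0
  ifelse(not_rec, "not_recommended", ifelse(rec, "recommended", "neutral"))
}

RECOMMENDATION_RANK <- c(recommended = 3L, neutral = 2L, not_recommended = 1L)

#' Choose the strand to tile for one SNP
#'
#' The strand with the better recommendation class wins (recommended >
#' neutral > not_recommended); on equal class the higher p-convert wins; on
#' an exact tie the forward strand is tiled (deterministic tie-break).
#'
#' @param forward,reverse lists (or one-row data frames) with at least
#'   `recommendation` and `p_convert`.
#' @return "forward" or "reverse".
#' @export
tile_strand <- function(forward, reverse) {
  rf <- RECOMMENDATION_RANK[[forward$recommendation]]
  rr <- RECOMMENDATION_RANK[[reverse$recommendation]]
  if (rf != rr) return(if (rf > rr) "forward" else "reverse")
  if (forward$p_convert != reverse$p_convert)
    return(if (forward$p_convert > reverse$p_convert) "forward" else "reverse")
  "forward"
}

#' Exclude [A/T] and [C/G] SNPs
#'
#' Complement-symmetric allele pairs need twice as many array features (the
#' two strands are indistinguishable), so SNPs whose ref/alt pair is {A,T} or
#' {C,G} in either order are removed.
#'
#' @param snps data frame with `ref_allele` and `alt_allele`.
#' @return the kept subset.
#' @export
exclude_transversion_ambiguous <- function(snps) {
  pair <- paste(pmin(snps$ref_allele, snps$alt_allele),
                pmax(snps$ref_allele, snps$alt_allele))
  snps[!(pair %in% c("A T", "C G")), , drop = FALSE]
}

#' Score and tile probes for a set of filtered SNPs
#'
#' Builds the forward (flank + ref + flank) and reverse (reverse-complement)
#' probe contexts, computes per-strand metrics — wobbles are other known
#' variants from the candidate table falling within the 71-base context,
#' wobble distance is measured from the target SNP, homopolymer runs of >= 6
#' bases are counted, and duplicate counts come from the uniqueness check —
#' then scores both strands, classifies them, and records the tiled strand.
#'
#' @param snps filtered candidate data frame (optionally with a
#'   `duplicate_count` column from [uniqueness_check()]).
#' @param known_variants optional data frame of all known variant positions
#'   (`pseudomolecule`, `position`) used for wobble metrics; defaults to
#'   `snps` itself.
#' @return `snps` with columns `wobble_count`, `wobble_distance`,
#'   `poly_count`, `p_convert_forward`, `p_convert_reverse`,
#'   `recommendation_forward`, `recommendation_reverse`, `tiled_strand`,
#'   `p_convert`, `recommendation`.
#' @export
score_and_tile <- function(snps, known_variants = NULL) {
  if (is.null(known_variants)) known_variants <- snps
  n <- nrow(snps)
  dup <- if ("duplicate_count" %in% names(snps)) snps$duplicate_count else
    rep(0L, n)
  ctx_f <- probe_context(snps)
  ctx_r <- reverse_complement(ctx_f)

  wob_n <- integer(n)
  wob_d <- rep(Inf, n)
  kv <- split(known_variants$position, known_variants$pseudomolecule)
  for (i in seq_len(n)) {
    pos <- kv[[snps$pseudomolecule[i]]]
    d <- abs(pos - snps$position[i])
    d <- d[d > 0 & d <= 35]
    wob_n[i] <- length(d)
    if (length(d)) wob_d[i] <- min(d)
  }
  poly <- count_homopolymer_runs(ctx_f)

  pf <- score_probe(ctx_f, dup, wob_n, poly)
  pr <- score_probe(ctx_r, dup, wob_n, poly)
  rf <- classify_recommendation(pf, dup, poly, wob_n, wob_d)
  rr <- classify_recommendation(pr, dup, poly, wob_n, wob_d)
  tiled <- vapply(seq_len(n), function(i) {
    tile_strand(list(recommendation = rf[i], p_convert = pf[i]),
                list(recommendation = rr[i], p_convert = pr[i]))
  }, character(1))

  snps$wobble_count <- wob_n
  snps$wobble_distance <- wob_d
  snps$poly_count <- poly
  snps$duplicate_count <- dup
  snps$p_convert_forward <- pf
  snps$p_convert_reverse <- pr
  snps$recommendation_forward <- rf
  snps$recommendation_reverse <- rr
  snps$tiled_strand <- tiled
  snps$p_convert <- ifelse(tiled == "forward", pf, pr)
  snps$recommendation <- ifelse(tiled == "forward", rf, rr)
  snps
}

#' Select a genome-balanced array manifest
#'
#' Trait-linked SNPs are included first unconditionally (unless they are
#' [A/T] or [C/G], which are excluded before anything else). The remaining
#' quota is distributed across pseudomolecules proportionally to their
#' lengths (largest-remainder rounding); within each pseudomolecule SNPs are
#' taken recommended before neutral before not_recommended, then by
#' descending p-convert, then by ascending position. Shortfall on a
#' pseudomolecule with too few eligible SNPs is redistributed. The manifest
#' is returned ordered by pseudomolecule and position.
#'
#' @param scored output of [score_and_tile()].
#' @param target_size requested manifest size (> 0).
#' @param pm_lengths named vector of pseudomolecule lengths (bases; any
#'   proportional unit works).
#' @param effect optional data frame (`snp_id`, `category`) merged in as
#'   `effect_category`.
#' @return manifest data frame (one row per snp_id).
#' @export
select_array <- function(scored, target_size, pm_lengths, effect = NULL) {
  if (target_size <= 0) stop("target_size must be > 0")
  eligible <- exclude_transversion_ambiguous(scored)
  picked <- eligible[eligible$trait_linked, , drop = FALSE]
  rest <- eligible[!eligible$trait_linked, , drop = FALSE]
  quota_total <- max(0L, min(target_size, nrow(eligible)) - nrow(picked))

  pms <- names(pm_lengths)
  avail <- split(rest, factor(rest$pseudomolecule, levels = pms))
  avail <- lapply(avail, function(df) {
    df[order(-RECOMMENDATION_RANK[df$recommendation], -df$p_convert,
             df$position), , drop = FALSE]
  })
  n_avail <- vapply(avail, nrow, integer(1))
  take <- setNames(integer(length(pms)), pms)
  remaining <- quota_total
  repeat {
    open <- n_avail - take > 0
    if (remaining == 0 || !any(open)) break
    w <- pm_lengths[pms]
    w[!open] <- 0
    exact <- remaining * w / sum(w)
    add <- floor(exact)
    rem <- remaining - sum(add)
    if (rem > 0) {
      frac_order <- order(-(exact - add), pms)[seq_len(rem)]
      add[frac_order] <- add[frac_order] + 1
    }
    add <- pmin(add, n_avail - take)
    if (sum(add) == 0) {
      # pure shortfall round: hand remaining slots to pseudomolecules in order
      for (p in order(-(n_avail - take))) {
        if (remaining == 0) break
        room <- n_avail[p] - take[p]
        give <- min(room, remaining)
        take[p] <- take[p] + give
        remaining <- remaining - give
      }
      break
    }
    take <- take + add
    remaining <- remaining - sum(add)
  }
  sel <- do.call(rbind, lapply(seq_along(pms), function(k) {
    if (take[k] == 0) return(NULL)
    avail[[k]][seq_len(take[k]), , drop = FALSE]
  }))
  manifest <- rbind(picked, sel)
  manifest <- manifest[order(manifest$pseudomolecule, manifest$position), ,
                       drop = FALSE]
  if (!is.null(effect)) {
    manifest$effect_category <-
      effect$category[match(manifest$snp_id, effect$snp_id)]
  }
  rownames(manifest) <- NULL
  manifest
}
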