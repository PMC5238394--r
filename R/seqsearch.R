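# Seed-and-verify placement search for probe contexts.
#
# Contract: a genomic placement of a 71-base context qualifies when the
# ungapped full-overlap alignment at that offset has identity >= min_identity,
# OR contains a contiguous exact-match run >= min_aligned bases; the overlap
# itself must be >= min_aligned. Candidate offsets come from exact 12-mer
# seeds: five disjoint 12-mers tile the first 60 bases of a 71-base context,
# so by pigeonhole any placement with <= 4 mismatches (the 94% threshold) and
# any placement containing a 60-base exact run shares at least one exact seed
# with the context. Reverse-complement placements are found by querying the
# reverse-complemented context against the forward-strand index.

SEED_LEN <- 12L

base_codes <- local({
  lut <- integer(128)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  function(s) lut[utf8ToInt(s) + 1L]
})

# 2-bit rolling k-mer codes for every position of a sequence
kmer_codes <- function(b, K = SEED_LEN) {
  n <- length(b)
  if (n < K) return(integer(0))
  code <- numeric(n - K + 1L)
  for (j in seq_len(K)) code <- code * 4 + b[j:(n - K + j)]
  code
}

#' Build a seed index over both subgenomes
#'
#' Indexes every forward-strand 12-mer of both subgenome references for the
#' placement searches behind the homeolog and uniqueness filters. Build once
#' and pass to [flag_homeologous()], [uniqueness_check()] and
#' [run_filter_pipeline()].
#'
#' @param genomes list with named character vectors `A` and `B`.
#' @return an opaque index object.
#' @export
build_genome_index <- function(genomes) {
  tabs <- list()
  codes <- list(A = list(), B = list())
  for (sub in c("A", "B")) {
    for (p in names(genomes[[sub]])) {
      b <- base_codes(genomes[[sub]][[p]])
      codes[[sub]][[p]] <- b
      kc <- kmer_codes(b)
      tabs[[length(tabs) + 1L]] <- data.table::data.table(
        code = kc, sub = sub, pm = p, pos = seq_along(kc))
    }
  }
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, code)
  structure(list(dt = dt, codes = codes, seqs = genomes), class = "genome_index")
}

longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# All qualifying placements of each context. `contexts` is a character vector
# (typically 71 bases); returns a data.table with one row per qualifying
# placement: qid, sub, pm, start (position of context base 1 on the forward
# strand), strand, identity, max_run, overlap, snp_base (the aligned genome
# base at `snp_offset`, reported in context orientation).
find_placements <- function(contexts, index, min_identity = 0.94,
                            min_aligned = 60L, snp_offset = 36L) {
  stopifnot(inherits(index, "genome_index"))
  queries <- list()
  qseqs <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") contexts else reverse_complement(contexts)
    for (qi in seq_along(qs)) {
      w <- nchar(qs[qi])
      offs <- unique(c(seq(1L, w - SEED_LEN + 1L, by = SEED_LEN), w - SEED_LEN + 1L))
      b <- base_codes(qs[qi])
      sc <- vapply(offs, function(o) {
        code <- 0
        for (j in 0:(SEED_LEN - 1L)) code <- code * 4 + b[o + j]
        code
      }, numeric(1))
      queries[[length(queries) + 1L]] <- data.table::data.table(
        qid = qi, strand = strand, off = offs, code = sc)
      qseqs[[paste(strand, qi)]] <- b
    }
  }
  qdt <- data.table::rbindlist(queries)
  hits <- index$dt[qdt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) {
    return(data.table::data.table(qid = integer(), sub = character(),
                                  pm = character(), start = integer(),
                                  strand = character(), identity = numeric(),
                                  max_run = integer(), overlap = integer(),
                                  snp_base = character()))
  }
  hits[, start := pos - off + 1L]
  pl <- unique(hits[, list(qid, strand, sub, pm, start)])

  out <- vector("list", nrow(pl))
  for (r in seq_len(nrow(pl))) {
    qb <- qseqs[[paste(pl$strand[r], pl$qid[r])]]
    w <- length(qb)
    gb <- index$codes[[pl$sub[r]]][[pl$pm[r]]]
    L <- length(gb)
    s <- pl$start[r]
    gs <- max(1L, s); ge <- min(L, s + w - 1L)
    overlap <- ge - gs + 1L
    if (overlap < min_aligned) next
    qseg <- qb[(gs - s + 1L):(ge - s + 1L)]
    eq <- qseg == gb[gs:ge]
    identity <- mean(eq)
    max_run <- longest_true_run(eq)
    if (identity < min_identity && max_run < min_aligned) next
    # aligned genome base at the SNP column, in context orientation
    sp <- if (pl$strand[r] == "+") snp_offset else w - snp_offset + 1L
    gpos <- s + sp - 1L
    snp_base <- if (gpos >= 1L && gpos <= L)
      substr(index$seqs[[pl$sub[r]]][[pl$pm[r]]], gpos, gpos) else NA_character_
    if (!is.na(snp_base) && pl$strand[r] == "-")
      snp_base <- complement_base(snp_base)
    out[[r]] <- data.table::data.table(
      qid = pl$qid[r], sub = pl$sub[r], pm = pl$pm[r], start = s,
      strand = pl$strand[r], identity = identity, max_run = max_run,
      overlap = overlap, snp_base = snp_base)
  }
  res <- data.table::rbindlist(out)
  if (!nrow(res)) {
    res <- data.table::data.table(qid = integer(), sub = character(),
                                  pm = character(), start = integer(),
                                  strand = character(), identity = numeric(),
                                  max_run = integer(), overlap = integer(),
                                  snp_base = character())
  }
  res
}

probe_context <- function(candidates) {
  paste0(candidates$flank_left,
         substr(candidates$ref_allele, 1, 1),
         candidates$flank_right)
}
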