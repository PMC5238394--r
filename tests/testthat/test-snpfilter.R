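test_that("ledger constructor enforces conservation and non-negativity", {
  l <- filter_ledger(100, discarded_identical = 5, discarded_both_genomes = 20)
  expect_equal(l$passed, 75)
  expect_error(filter_ledger(10, discarded_identical = 20), "conservation")
  expect_error(filter_ledger(10, discarded_identical = -1), ">= 0")
  expect_error(filter_ledger(100, discarded_both_genomes = 20, passed = 90),
               "conservation")
})

test_that("identical records collapse to one; same locus different alts survive", {
  a <- make_candidate("S1", "A", "A01", 100, "A", "C")
  b <- make_candidate("S2", "A", "A01", 100, "A", "C")
  d <- dedupe_identical(rbind(a, b))
  expect_equal(nrow(d$kept), 1)
  expect_equal(d$n_removed, 1)
  expect_equal(d$kept$snp_id, "S1")  # first occurrence kept

  c2 <- make_candidate("S3", "A", "A01", 100, "A", "T")
  d2 <- dedupe_identical(rbind(a, c2))
  expect_equal(nrow(d2$kept), 2)

  planted <- rbind(a, a, b, b, c2)  # 3 redundant copies
  expect_equal(dedupe_identical(planted)$n_removed, 3)
})

test_that("homeolog flag fires exactly on divergence-explained alternates", {
  # hand-built pair: B is A with one substitution at the SNP site
  set.seed(42)
  A01 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  B01 <- A01
  ref <- substr(A01, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  substr(B01, 200, 200) <- alt
  genomes <- list(A = c(A01 = A01), B = c(B01 = B01))
  cand <- candidates_from_genome(genomes, "A", "A01", 200, alt)
  hf <- flag_homeologous(cand, genomes)
  expect_true(hf$flagged)

  # same locus but the alternate is NOT the homeologous base
  other_alt <- setdiff(c("A", "C", "G", "T"), c(ref, alt))[1]
  cand2 <- candidates_from_genome(genomes, "A", "A01", 200, other_alt)
  expect_false(flag_homeologous(cand2, genomes)$flagged)

  # short flank at the pseudomolecule edge is unevaluable
  cand3 <- make_candidate("E1", "A", "A01", 10, substr(A01, 10, 10), "A",
                          flank_left = substr(A01, 1, 9),
                          flank_right = substr(A01, 11, 45))
  hf3 <- flag_homeologous(cand3, genomes)
  expect_true(hf3$unevaluable)
})

test_that("at high divergence no cross-alignment qualifies and nothing is flagged", {
  cfg <- small_sim_config(homeolog_divergence = 0.3, n_homeolog_artifacts = 0,
                          n_true_snps = 50, n_duplicated_flank_snps = 0,
                          n_multiallelic = 0, seed = 5)
  g <- generate_genomes(cfg)
  cc <- generate_candidates(g$genomes, g$annotation, cfg)
  hf <- flag_homeologous(cc$candidates, cc$genomes)
  expect_equal(sum(hf$flagged), 0)
})

test_that("gene-proximity filter keeps the 10-kb window inclusive", {
  ann <- data.frame(seqid = "A01", type = "gene", start = 5001, end = 6000,
                    strand = "+", gene_id = "g1", transcript_id = NA)
  cand <- rbind(make_candidate("S1", "A", "A01", 1, "A", "C"),      # 5,000 away
                make_candidate("S2", "A", "A01", 4000, "A", "C"),   # 1,001 away
                make_candidate("S3", "A", "A01", 16001, "A", "C"))  # 10,001 away
  ng <- filter_near_genes(cand, ann, window = 10000)
  expect_equal(ng$kept$snp_id, c("S1", "S2"))
  expect_equal(ng$n_removed, 1)

  # exactly 10,000 bases from the gene end is kept; inside a gene trivially so
  cand2 <- rbind(make_candidate("B1", "A", "A01", 16000, "A", "C"),
                 make_candidate("B2", "A", "A01", 5500, "A", "C"))
  expect_equal(filter_near_genes(cand2, ann)$kept$snp_id, c("B1", "B2"))

  # unknown pseudomolecule dropped with a warning, counted apart
  cand3 <- make_candidate("U1", "A", "A99", 100, "A", "C")
  expect_warning(ng3 <- filter_near_genes(cand3, ann), "absent")
  expect_equal(ng3$n_unplaced, 1)
})

test_that("uniqueness check agrees with the exhaustive sliding-window oracle", {
  set.seed(11)
  A01 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  a <- strsplit(A01, "", fixed = TRUE)[[1]]
  mut <- which(runif(2000) < 0.05)
  a[mut] <- vapply(a[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  B01 <- paste(a, collapse = "")
  # plant a verbatim copy of the context at position 500 into position 1500,
  # and a reverse-complemented 60-base core of the context at 800 into 1200
  ctx500 <- substr(A01, 465, 535)
  substr(A01, 1500, 1570) <- ctx500
  core800 <- reverse_complement(substr(A01, 771, 830))
  substr(A01, 1200, 1259) <- core800
  genomes <- list(A = c(A01 = A01), B = c(B01 = B01))

  positions <- c(500, 800, 100, 300, 1000)
  cand <- candidates_from_genome(genomes, "A", "A01", positions,
                                 rep("A", length(positions)))
  cand$alt_allele <- vapply(cand$ref_allele, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  uq <- uniqueness_check(cand, genomes)
  expect_true(all(uq$self_found))
  expect_equal(uq$is_unique, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(uq$duplicate_count[1:2], c(1L, 1L))

  # oracle comparison: qualifying placements minus self and one homeologous
  # counterpart must equal the reported duplicate count
  for (i in seq_len(nrow(cand))) {
    ctx <- paste0(cand$flank_left[i], cand$ref_allele[i], cand$flank_right[i])
    pl <- oracle_placements(ctx, genomes)
    self <- pl$sub == "A" & pl$strand == "+" & pl$start == cand$position[i] - 35
    n_other <- sum(pl$sub == "B")
    dup_oracle <- sum(!self & pl$sub == "A") + max(0L, n_other - 1L)
    expect_equal(uq$duplicate_count[i], dup_oracle, label = cand$snp_id[i])
  }
})

test_that("ambiguous and multiallelic candidates are removed", {
  a <- make_candidate("S1", "A", "A01", 100, "A", "C")
  b <- make_candidate("S2", "A", "A01", 100, "A", "T")   # same locus, 3rd allele
  c3 <- make_candidate("S3", "A", "A01", 300, "A", "N")  # ambiguous symbol
  d4 <- make_candidate("S4", "A", "A01", 400, "G", "C,T", multiallelic = TRUE)
  e5 <- make_candidate("S5", "A", "A01", 500, "G", "A")
  am <- remove_ambiguous_multiallelic(rbind(a, b, c3, d4, e5))
  expect_equal(am$kept$snp_id, "S5")
  expect_equal(am$n_removed, 4)

  # 5 planted multiallelic loci written as two expanded rows each
  rows <- do.call(rbind, lapply(1:5, function(k) rbind(
    make_candidate(sprintf("M%da", k), "A", "A01", 1000 + k, "A", "C",
                   multiallelic = TRUE),
    make_candidate(sprintf("M%db", k), "A", "A01", 1000 + k, "A", "G",
                   multiallelic = TRUE))))
  expect_equal(remove_ambiguous_multiallelic(rows)$n_removed, 10)
})

test_that("the cascade recovers planted truth exactly and conserves the ledger", {
  run <- small_run()
  oc <- truth_outcomes(run)
  expect_equal(oc$outcome, unname(expected_outcome[oc$label]))
  expect_equal(run$filter$ledger$passed, run$config$n_true_snps)

  l <- run$filter$ledger
  expect_equal(l$input,
               l$passed + l$discarded_identical + l$discarded_both_genomes +
                 l$discarded_both_strands + l$discarded_far_from_gene +
                 l$discarded_flank_unevaluable + l$discarded_self_match_failed +
                 l$discarded_ambiguous_multiallelic)
})

test_that("the cascade is idempotent and handles empty input", {
  run <- small_run()
  again <- run_filter_pipeline(run$filter$passed, run$genomes, run$annotation)
  expect_equal(nrow(again$passed), nrow(run$filter$passed))
  expect_equal(again$ledger$passed, again$ledger$input)

  empty <- run$candidates[0, , drop = FALSE]
  fe <- run_filter_pipeline(empty, run$genomes, run$annotation)
  expect_equal(unlist(fe$ledger), setNames(rep(0, 9), names(unlist(fe$ledger))))
})

test_that("dedupe and multiallelic removal commute on random fixtures", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    cand <- do.call(rbind, lapply(seq_len(n), function(i) {
      alt <- if (runif(1) < 0.2) "C,T" else sample(c("C", "T"), 1)
      make_candidate(sprintf("R%02d", i), "A", "A01",
                     sample(1:8, 1) * 100,
                     sample(c("A", "G"), 1), alt,
                     multiallelic = grepl(",", alt, fixed = TRUE))
    }))
    path1 <- remove_ambiguous_multiallelic(dedupe_identical(cand)$kept)$kept
    path2 <- dedupe_identical(remove_ambiguous_multiallelic(cand)$kept)$kept
    expect_equal(nrow(path1), nrow(path2))
    expect_setequal(path1$snp_id, path2$snp_id)
  }
})
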