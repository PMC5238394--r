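gm_calls <- function(calls, category = NULL) {
  rownames(calls) <- sprintf("S%02d", seq_len(nrow(calls)))
  colnames(calls) <- sprintf("M%03d", seq_len(ncol(calls)))
  samples <- data.frame(sample = rownames(calls), species = "A. hypogaea",
                        ploidy = "tetraploid",
                        category = category %||% rep("hypogaea", nrow(calls)),
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, samples, data.frame(snp_id = colnames(calls)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele-sharing distance hits its closed-form anchors", {
  # three clonal samples -> all pairwise distances zero
  gm <- gm_calls(matrix(rep(c(0L, 1L, 2L, 0L), 3), 3, byrow = TRUE))
  D <- allele_sharing_distance(gm)
  expect_true(all(D == 0))

  # opposite homozygotes across every SNP -> distance 1
  gm2 <- gm_calls(rbind(rep(0L, 10), rep(2L, 10)))
  expect_equal(allele_sharing_distance(gm2)[1, 2], 1)

  expect_error(allele_sharing_distance(gm_calls(matrix(0L, 1, 3))),
               "at least 2")
})

test_that("vectorised distances equal the naive per-pair loop", {
  set.seed(23)
  for (rep in 1:10) {
    gm <- random_genotype_matrix(sample(4:10, 1), sample(10:40, 1))
    D <- allele_sharing_distance(gm)
    expect_equal(D, oracle_distance(gm$calls))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    ok <- !is.na(D)
    expect_true(all(D[ok] >= 0 & D[ok] <= 1))
  }
  # triangle inequality holds on complete matrices (with missing calls the
  # per-pair SNP subsets differ and metricity is not guaranteed)
  for (rep in 1:10) {
    gm <- random_genotype_matrix(sample(4:8, 1), sample(10:30, 1), missing = 0)
    D <- allele_sharing_distance(gm)
    n <- nrow(D)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      expect_true(D[i, k] <= D[i, j] + D[j, k] + 1e-12)
    }
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # fixed 4-taxon additive matrix from tree ((a:1,b:2):1,(c:3,d:4))
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["a", "c"] <- D["c", "a"] <- 5
  D["a", "d"] <- D["d", "a"] <- 6
  D["b", "c"] <- D["c", "b"] <- 6
  D["b", "d"] <- D["d", "b"] <- 7
  D["c", "d"] <- D["d", "c"] <- 7
  tr <- neighbor_joining(D)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), colnames(D)],
               D)
  # a and b are siblings in the recovered topology
  mrca_ab <- ape::getMRCA(ape::root(tr, "d", resolve.root = TRUE), c("a", "b"))
  expect_equal(length(ape::extract.clade(
    ape::root(tr, "d", resolve.root = TRUE), mrca_ab)$tip.label), 2)

  # three taxa: closed-form branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), sort(c(1, 2, 3)))

  expect_error(neighbor_joining(D3[1:2, 1:2]), "at least 3")
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(neighbor_joining(Dna), "incomplete")
})

test_that("random additive matrices are recovered topologically for n <= 8", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.5, 3)
    D <- as.matrix(ape::cophenetic.phylo(tr0))
    tr1 <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr0), ape::unroot(tr1)), 0)
  }
})

test_that("tree cutting isolates planted groups and degenerates to singletons", {
  # two tight groups far apart
  set.seed(13)
  calls <- rbind(matrix(0L, 4, 40), matrix(2L, 4, 40))
  noise <- matrix(sample(0:1, 80, replace = TRUE), 8, 10)
  calls <- cbind(calls, noise)
  storage.mode(calls) <- "integer"
  gm <- gm_calls(calls)
  tr <- neighbor_joining(allele_sharing_distance(gm))
  cl <- assign_clusters(tr, 2)
  expect_equal(length(unique(cl[sprintf("S%02d", 1:4)])), 1)
  expect_equal(length(unique(cl[sprintf("S%02d", 5:8)])), 1)
  expect_false(cl[["S01"]] == cl[["S05"]])

  cl_all <- assign_clusters(tr, 8)
  expect_equal(length(unique(cl_all)), 8)
  expect_error(assign_clusters(tr, 1), "k must be")
})

test_that("the default panel isolates wild accessions in one cluster", {
  run <- small_run()
  cl <- run$clusters
  truth <- run$panel_truth$clusters[names(cl)]
  wild_ids <- names(cl)[truth == "wild"]
  expect_equal(length(unique(cl[wild_ids])), 1)
  expect_false(any(cl[setdiff(names(cl), wild_ids)] %in% cl[wild_ids]))
  expect_equal(run$truth_eval$cluster_purity, 1)
})

test_that("category frequencies match the naive per-category loop", {
  calls <- rbind(rep(2L, 5), rep(2L, 5),      # wild: all alt-homozygous
                 rep(1L, 5), rep(1L, 5),      # fastigiata: all het
                 rep(0L, 5), c(0L, 1L, 2L, -1L, 0L))
  gm <- gm_calls(calls, category = c("wild", "wild", "fastigiata",
                                     "fastigiata", "hypogaea", "hypogaea"))
  fr <- category_frequencies(gm)
  expect_equal(fr$freq_wild, rep(1, 5))
  expect_equal(fr$freq_fastigiata, rep(0.5, 5))
  expect_equal(fr$freq_hypogaea, c(0, 0.25, 0.5, 0, 0))
  expect_equal(fr$n_hypogaea, c(2L, 2L, 2L, 1L, 2L))

  set.seed(7)
  gmr <- random_genotype_matrix(9, 25)
  frr <- category_frequencies(gmr)
  for (cat in unique(gmr$samples$category)) {
    rows <- gmr$samples$category == cat
    naive <- vapply(seq_len(ncol(gmr$calls)), function(j) {
      v <- gmr$calls[rows, j]; v <- v[v != -1L]
      if (!length(v)) NA_real_ else sum(v) / (2 * length(v))
    }, numeric(1))
    expect_equal(frr[[paste0("freq_", cat)]], naive)
  }
})

test_that("the specificity scan follows its contrast rule and is threshold-monotone", {
  fr <- data.frame(snp_id = c("a", "b", "c", "d"),
                   freq_fastigiata = c(0.95, 0.02, 0.5, 0.85),
                   freq_hypogaea = c(0.02, 0.95, 0.5, 0.5),
                   freq_wild = c(0.01, 0.90, 0.5, 0.0))
  sc <- specific_high_frequency_scan(fr, 0.80)
  expect_equal(sc$snps$class,
               c("fastigiata_specific", "hypogaea_specific", "none", "none"))
  expect_equal(sc$snps$shared_with_wild, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(sc$counts$total_specific, 2)
  expect_equal(sc$counts$hypogaea_shared_with_wild, 1)

  # raising the threshold never adds a specific SNP
  set.seed(3)
  frr <- data.frame(snp_id = sprintf("s%03d", 1:200),
                    freq_fastigiata = runif(200), freq_hypogaea = runif(200),
                    freq_wild = runif(200))
  prev <- specific_high_frequency_scan(frr, 0.5)$snps$class != "none"
  for (th in c(0.6, 0.7, 0.8, 0.9, 0.99)) {
    cur <- specific_high_frequency_scan(frr, th)$snps$class != "none"
    expect_true(all(!cur | prev))
    prev <- cur
  }
})

test_that("planted extremes give scan sensitivity and specificity of 1", {
  run <- small_run()
  cfg <- small_sim_config(missing_rate = 0, n_planted_specific = 0,
                          n_sublineage_snps = 0, seed = 19)
  idx_fast <- 1:10; idx_hyp <- 11:20
  pp <- generate_panel(run$manifest, cfg, freq_override = function(fr) {
    bg <- seq_along(fr$fastigiata)
    fr$fastigiata[bg] <- 0.05; fr$hypogaea[bg] <- 0.05; fr$wild[bg] <- 0.05
    fr$fastigiata[idx_fast] <- 1; fr$hypogaea[idx_fast] <- 0; fr$wild[idx_fast] <- 0
    fr$hypogaea[idx_hyp] <- 1; fr$fastigiata[idx_hyp] <- 0; fr$wild[idx_hyp] <- 0
    fr
  })
  fr <- category_frequencies(pp$panel)
  sc <- specific_high_frequency_scan(fr, 0.80)
  planted <- run$manifest$snp_id[c(idx_fast, idx_hyp)]
  called <- sc$snps$snp_id[sc$snps$class != "none"]
  expect_setequal(called, planted)  # sensitivity and specificity both 1
})

test_that("effect filtering keeps missense and nonsense scan hits only", {
  scan_df <- data.frame(snp_id = sprintf("x%d", 1:7),
                        class = c(rep("hypogaea_specific", 6), "none"),
                        shared_with_wild = FALSE, stringsAsFactors = FALSE)
  ann <- data.frame(
    snp_id = sprintf("x%d", 1:7),
    category = c("non_synonymous_coding", "non_synonymous_coding",
                 "non_synonymous_coding", "stop_gained", "synonymous_coding",
                 "non_synonymous_coding", "stop_gained"),
    gene_id = c("g1", "g1", "g2", "g3", "g4", "g4", "g5"),
    stringsAsFactors = FALSE)
  out <- scan_effect_filter(scan_df, ann)
  expect_equal(nrow(out$snps), 5)          # x5 synonymous out, x7 not specific
  expect_equal(out$genes, c("g1", "g2", "g3", "g4"))
  expect_equal(sum(out$snps$effect_class == "high"), 1)
})
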