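# Hand-built single-gene genome for exact codon cases.
# Layout on A01 (1-based): 1..30 upstream, gene 31..130:
#   5'UTR 31..40, CDS exon1 41..70, intron 71..90, CDS exon2 91..120,
#   3'UTR 121..130. CDS = 60 bases = 20 codons.
toy_gene_genome <- function(cds, strand = "+") {
  stopifnot(nchar(cds) == 60)
  up <- strrep("T", 30); utr5 <- strrep("C", 10); intron <- strrep("A", 20)
  utr3 <- strrep("G", 10); down <- strrep("T", 30)
  if (strand == "+") {
    seg1 <- substr(cds, 1, 30); seg2 <- substr(cds, 31, 60)
    seqs <- paste0(up, utr5, seg1, intron, seg2, utr3, down)
    utr5_c <- c(31, 40); cds1 <- c(41, 70); cds2 <- c(91, 120); utr3_c <- c(121, 130)
    exon1 <- c(31, 70); exon2 <- c(91, 130)
  } else {
    # transcript runs right to left: 5'UTR at the right end
    seg1 <- reverse_complement(substr(cds, 1, 30))   # rightmost CDS block
    seg2 <- reverse_complement(substr(cds, 31, 60))
    seqs <- paste0(up, utr3, seg2, intron, seg1, utr5, down)
    utr3_c <- c(31, 40); cds2 <- c(41, 70); cds1 <- c(91, 120); utr5_c <- c(121, 130)
    exon1 <- c(91, 130); exon2 <- c(31, 70)
  }
  ann <- data.frame(
    seqid = "A01",
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS",
             "five_prime_UTR", "three_prime_UTR"),
    start = c(31, 31, exon1[1], exon2[1], cds1[1], cds2[1], utr5_c[1], utr3_c[1]),
    end = c(130, 130, exon1[2], exon2[2], cds1[2], cds2[2], utr5_c[2], utr3_c[2]),
    strand = strand, gene_id = "g1", transcript_id = "g1.1",
    stringsAsFactors = FALSE)
  list(genomes = list(A = c(A01 = seqs), B = character(0)), annotation = ann)
}

toy_cds <- paste0("ATG", "GGA", "TGG", "AAA", strrep("GCT", 15), "TAA")

snp_row <- function(pm, pos, ref, alt) {
  data.frame(snp_id = "X1", pseudomolecule = pm, position = pos,
             ref_allele = ref, alt_allele = alt, stringsAsFactors = FALSE)
}

test_that("codon-level categories follow the genetic code", {
  g <- toy_gene_genome(toy_cds)
  # codon 2 GGA -> GGG (Gly/Gly): CDS position 6 = genomic 46
  eff <- classify_effect(snp_row("A01", 46, "A", "G"), g$annotation, g$genomes)
  expect_equal(eff$category, "synonymous_coding")
  expect_equal(eff$codon_change, "GGA/GGG")
  # codon 3 TGG -> TGA mid-CDS: CDS position 9 = genomic 49
  eff <- classify_effect(snp_row("A01", 49, "G", "A"), g$annotation, g$genomes)
  expect_equal(eff$category, "stop_gained")
  # codon 4 AAA -> GAA (Lys -> Glu): CDS pos 10 = genomic 50
  eff <- classify_effect(snp_row("A01", 50, "A", "G"), g$annotation, g$genomes)
  expect_equal(eff$category, "non_synonymous_coding")
  # initiator ATG -> GTG: CDS pos 1 = genomic 41
  eff <- classify_effect(snp_row("A01", 41, "A", "G"), g$annotation, g$genomes)
  expect_equal(eff$category, "start_lost")
  # codon 2 GGA -> GAA: adjacent to the start
  eff <- classify_effect(snp_row("A01", 45, "G", "A"), g$annotation, g$genomes)
  expect_equal(eff$category, "non_synonymous_start")
  # terminal stop TAA -> CAA: CDS pos 58 = exon2 offset 28 = genomic 118
  eff <- classify_effect(snp_row("A01", 118, "T", "C"), g$annotation, g$genomes)
  expect_equal(eff$category, "stop_lost")
  # penultimate codon GCT -> ACT: CDS pos 55 = genomic 115
  eff <- classify_effect(snp_row("A01", 115, "G", "A"), g$annotation, g$genomes)
  expect_equal(eff$category, "non_synonymous_stop")
  # intron, UTRs, intergenic
  expect_equal(classify_effect(snp_row("A01", 80, "A", "G"),
                               g$annotation, g$genomes)$category, "intron")
  expect_equal(classify_effect(snp_row("A01", 35, "C", "G"),
                               g$annotation, g$genomes)$category, "UTR_5_prime")
  expect_equal(classify_effect(snp_row("A01", 125, "G", "A"),
                               g$annotation, g$genomes)$category, "UTR_3_prime")
  expect_equal(classify_effect(snp_row("A01", 10, "T", "A"),
                               g$annotation, g$genomes)$category, "intergenic")
  expect_error(classify_effect(snp_row("A01", 9999, "A", "G"),
                               g$annotation, g$genomes), "beyond")
})

test_that("a reverse-strand CDS classifies like its forward construction", {
  gf <- toy_gene_genome(toy_cds, "+")
  gr <- toy_gene_genome(toy_cds, "-")
  # CDS position 9 (TGG -> TGA, stop gained): forward genomic 49;
  # reverse layout: CDS block1 91..120 right-to-left, cds pos 9 -> genomic 112,
  # alleles complemented
  f <- classify_effect(snp_row("A01", 49, "G", "A"), gf$annotation, gf$genomes)
  r <- classify_effect(snp_row("A01", 112, "C", "T"), gr$annotation, gr$genomes)
  expect_equal(r$category, f$category)
  expect_equal(r$codon_change, f$codon_change)
  # synonymous case mirrored the same way: forward genomic 46 -> reverse 115
  f2 <- classify_effect(snp_row("A01", 46, "A", "G"), gf$annotation, gf$genomes)
  r2 <- classify_effect(snp_row("A01", 115, "T", "C"), gr$annotation, gr$genomes)
  expect_equal(r2$category, f2$category)
})

test_that("a CDS whose length is not a multiple of three falls into others", {
  g <- toy_gene_genome(toy_cds)
  ann <- g$annotation
  ann$end[ann$type == "CDS" & ann$start == 91] <- 119  # truncate exon2
  eff <- classify_effect(snp_row("A01", 46, "A", "G"), ann, g$genomes)
  expect_equal(eff$category, "others")
})

test_that("classifier agrees with the translate-and-compare oracle on random SNPs", {
  run <- small_run()
  ann <- run$annotation
  genomes <- run$genomes
  seqs <- c(genomes$A, genomes$B)
  mrna <- ann[ann$type == "mRNA", ]
  set.seed(31)
  n_cases <- 400
  picks <- mrna[sample(nrow(mrna), n_cases, replace = TRUE), ]
  pos <- floor(runif(n_cases, picks$start - 50, picks$end + 51))
  pos <- pmax(1, pmin(pos, nchar(seqs[[1]])))
  snps <- data.frame(
    snp_id = sprintf("R%04d", seq_len(n_cases)),
    pseudomolecule = picks$seqid, position = pos,
    ref_allele = vapply(seq_len(n_cases), function(i)
      substr(seqs[[picks$seqid[i]]], pos[i], pos[i]), character(1)),
    stringsAsFactors = FALSE)
  snps$alt_allele <- vapply(snps$ref_allele, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  got <- classify_effect(snps, ann, genomes)
  want <- vapply(seq_len(n_cases), function(i)
    oracle_effect(snps$pseudomolecule[i], snps$position[i],
                  snps$ref_allele[i], snps$alt_allele[i], ann, genomes),
    character(1))
  expect_equal(got$category, want)
  # categories partition the SNPs
  expect_false(any(is.na(got$category)))
  # codon change present exactly for coding categories
  coding <- got$category %in% c("synonymous_coding", "non_synonymous_coding",
                                "stop_gained", "stop_lost", "start_lost",
                                "non_synonymous_start", "non_synonymous_stop")
  expect_equal(!is.na(got$codon_change), coding)
})

test_that("annotation summary is additive, ordered, and zero on empty input", {
  empty <- summarize_annotation(data.frame(snp_id = character(),
                                           category = character()),
                                character(0))
  expect_true(all(empty[, c("A", "B", "both")] == 0))

  run <- small_run()
  eff <- run$effects[match(run$manifest$snp_id, run$effects$snp_id), ]
  s <- summarize_annotation(eff, run$manifest$subgenome)
  expect_equal(s$both, s$A + s$B)
  body <- s[s$category != "Total", ]
  expect_equal(body$category,
               c("synonymous_coding", "non_synonymous_coding", "intron",
                 "stop_gained", "stop_lost", "intergenic", "start_lost",
                 "non_synonymous_start", "non_synonymous_stop",
                 "UTR_3_prime", "UTR_5_prime", "others"))
  expect_equal(sum(body$both), nrow(run$manifest))
  expect_equal(s$both[s$category == "Total"], nrow(run$manifest))
})
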