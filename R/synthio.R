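#' Simulation configuration for the synthetic allotetraploid study
#'
#' Defines the conditions under which every synthetic input is generated: a
#' pair of homeologous subgenomes, gene models, a candidate-SNP pool
#' contaminated with known artifact classes, and a structured genotype panel.
#' Defaults emulate the design of a groundnut-style study at a computationally
#' tractable scale: 10 pseudomolecules per subgenome, a 5% fixed divergence
#' between subgenomes, a candidate pool dominated by genuine gene-proximal
#' SNPs plus homeolog-derived and duplicated-flank artifacts, and a 300-sample
#' panel of one wild group and two cultivated subspecies groups carrying
#' planted subspecies-specific high-frequency alleles.
#'
#' @param n_pseudomolecules_per_subgenome pseudomolecules per subgenome.
#' @param pseudomolecule_length bases per pseudomolecule (>= 200).
#' @param homeolog_divergence substitution fraction between subgenomes, in
#'   [0,1]. Sites are sampled uniformly.
#' @param n_genes total gene models, mirrored at identical coordinates on the
#'   two subgenomes (homeologous gene pairs).
#' @param n_true_snps genuine biallelic inter-accession SNPs within 10 kb of
#'   genes.
#' @param n_homeolog_artifacts candidates whose alternate allele is the
#'   homeologous subgenome base (subgenome divergence mistaken for
#'   polymorphism).
#' @param n_duplicated_flank_snps candidates whose probe context is copied
#'   elsewhere in the genome.
#' @param n_multiallelic candidate loci carrying more than two alleles.
#' @param n_trait_linked number of true SNPs flagged as trait-linked (given
#'   tiling priority during array selection).
#' @param n_wild,n_fastigiata,n_hypogaea panel sizes per category.
#' @param n_planted_specific planted subspecies-specific high-frequency SNPs
#'   per cultivated category.
#' @param n_sublineage_snps background SNPs at which half of the hypogaea
#'   samples (a planted sub-lineage) carry contrasting frequencies, giving
#'   the cultivated germplasm the internal substructure real panels show
#'   (one subspecies split over two clusters); 0 disables.
#' @param shared_wild_fraction fraction of the hypogaea-specific planted SNPs
#'   whose alternate allele is also at high frequency in the wild group
#'   (the wild-shared class); fastigiata-specific SNPs are never wild-shared.
#' @param missing_rate per-call missing probability in the panel.
#' @param inbreeding within-category inbreeding coefficient used when drawing
#'   genotypes (a predominantly selfing crop: heterozygotes are rare).
#' @param wild_divergence mixing weight in [0,1] pulling wild allele
#'   frequencies away from the shared cultivated background frequency, giving
#'   the wild group both higher diversity and genuine separation.
#' @param seed integer seed; all components derive their own sub-stream from
#'   it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pseudomolecules_per_subgenome = 10,
                       pseudomolecule_length = 100000,
                       homeolog_divergence = 0.05,
                       n_genes = 120,
                       n_true_snps = 2000,
                       n_homeolog_artifacts = 400,
                       n_duplicated_flank_snps = 100,
                       n_multiallelic = 50,
                       n_trait_linked = 20,
                       n_wild = 36,
                       n_fastigiata = 132,
                       n_hypogaea = 132,
                       n_planted_specific = 60,
                       n_sublineage_snps = 60,
                       shared_wild_fraction = 0.25,
                       missing_rate = 0.02,
                       inbreeding = 0.95,
                       wild_divergence = 0.5,
                       seed = 42L) {
  cfg <- list(
    n_pseudomolecules_per_subgenome = as.integer(n_pseudomolecules_per_subgenome),
    pseudomolecule_length = as.integer(pseudomolecule_length),
    homeolog_divergence = homeolog_divergence,
    n_genes = as.integer(n_genes),
    n_true_snps = as.integer(n_true_snps),
    n_homeolog_artifacts = as.integer(n_homeolog_artifacts),
    n_duplicated_flank_snps = as.integer(n_duplicated_flank_snps),
    n_multiallelic = as.integer(n_multiallelic),
    n_trait_linked = as.integer(n_trait_linked),
    n_wild = as.integer(n_wild),
    n_fastigiata = as.integer(n_fastigiata),
    n_hypogaea = as.integer(n_hypogaea),
    n_planted_specific = as.integer(n_planted_specific),
    n_sublineage_snps = as.integer(n_sublineage_snps),
    shared_wild_fraction = shared_wild_fraction,
    missing_rate = missing_rate,
    inbreeding = inbreeding,
    wild_divergence = wild_divergence,
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_pseudomolecules_per_subgenome", "pseudomolecule_length",
                  "n_genes", "n_true_snps", "n_homeolog_artifacts",
                  "n_duplicated_flank_snps", "n_multiallelic", "n_trait_linked",
                  "n_wild", "n_fastigiata", "n_hypogaea", "n_planted_specific",
                  "n_sublineage_snps")]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  fracs <- unlist(cfg[c("homeolog_divergence", "missing_rate", "inbreeding",
                        "wild_divergence", "shared_wild_fraction")])
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]")
  if (cfg$pseudomolecule_length < 200)
    stop("pseudomolecule_length must be >= 200 to leave room for probe flanks")
  if (cfg$n_trait_linked > cfg$n_true_snps)
    stop("n_trait_linked cannot exceed n_true_snps")
  class(cfg) <- "sim_config"
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# Genomic positions of a CDS in transcript (5'->3') order.
cds_genomic_positions <- function(blocks, strand) {
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(i) blocks$start[i]:blocks$end[i]))
  pos <- sort(pos)
  if (strand == "-") rev(pos) else pos
}

# Draw one gene model's structural dimensions.
sample_gene_structure <- function() {
  u5 <- sample(30:80, 1)
  n_codons <- sample(50:120, 1)
  cds_len <- 3L * n_codons
  e1 <- sample(30:(cds_len - 30), 1)
  intron <- sample(60:150, 1)
  u3 <- sample(30:80, 1)
  strand <- sample(c("+", "-"), 1)
  list(u5 = u5, cds_len = cds_len, e1 = e1, intron = intron, u3 = u3,
       strand = strand, span = u5 + cds_len + intron + u3)
}

sample_coding_sequence <- function(cds_len) {
  n_codons <- cds_len / 3L
  middle <- sample(setdiff(all_codons(), STOP_CODONS), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(middle, collapse = ""), sample(STOP_CODONS, 1))
}

# Feature rows (gene/mRNA/exon/CDS/UTRs) for one gene, plus the genomic
# segments of coding sequence to write into the reference.
layout_gene <- function(seqid, gene_id, gstart, st) {
  gend <- gstart + st$span - 1L
  tid <- paste0(gene_id, ".1")
  if (st$strand == "+") {
    utr5 <- c(gstart, gstart + st$u5 - 1L)
    cds1 <- c(utr5[2] + 1L, utr5[2] + st$e1)
    intr <- c(cds1[2] + 1L, cds1[2] + st$intron)
    cds2 <- c(intr[2] + 1L, intr[2] + st$cds_len - st$e1)
    utr3 <- c(cds2[2] + 1L, gend)
    exon1 <- c(utr5[1], cds1[2])
    exon2 <- c(cds2[1], utr3[2])
    first_cds <- cds1; second_cds <- cds2
  } else {
    utr5 <- c(gend - st$u5 + 1L, gend)
    cds1 <- c(utr5[1] - st$e1, utr5[1] - 1L)
    intr <- c(cds1[1] - st$intron, cds1[1] - 1L)
    cds2 <- c(intr[1] - (st$cds_len - st$e1), intr[1] - 1L)
    utr3 <- c(gstart, cds2[1] - 1L)
    exon1 <- c(cds1[1], utr5[2])
    exon2 <- c(gstart, cds2[2])
    first_cds <- cds1; second_cds <- cds2
  }
  feat <- data.frame(
    seqid = seqid,
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS",
             "five_prime_UTR", "three_prime_UTR"),
    start = c(gstart, gstart, exon1[1], exon2[1], first_cds[1], second_cds[1],
              utr5[1], utr3[1]),
    end = c(gend, gend, exon1[2], exon2[2], first_cds[2], second_cds[2],
            utr5[2], utr3[2]),
    strand = st$strand,
    gene_id = gene_id,
    transcript_id = c(NA, tid, tid, tid, tid, tid, tid, tid),
    stringsAsFactors = FALSE
  )
  list(features = feat, first_cds = first_cds, second_cds = second_cds,
       gend = gend)
}

#' Generate a pair of homeologous subgenome references with gene models
#'
#' Subgenome A is drawn uniformly at random; subgenome B is a copy of A
#' substituted at `homeolog_divergence` of uniformly sampled sites (the fixed
#' divergence that creates homeologous SNP artifacts). Gene models with a
#' fixed minimal grammar (5' UTR, two CDS exons with an intact reading frame,
#' one intron, 3' UTR; one transcript per gene) are placed without overlap on
#' both strands, at identical coordinates on the two subgenomes (homeologous
#' gene pairs). Divergence mutations that would break a B-copy reading frame
#' (premature stop, damaged start or terminal stop codon) are reverted.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (list of named character vectors `A` and `B`),
#'   `annotation` (feature data frame with GFF3-style columns) and the config.
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genomes"), {
    n_pm <- config$n_pseudomolecules_per_subgenome
    L <- config$pseudomolecule_length
    pm_a <- sprintf("A%02d", seq_len(n_pm))
    pm_b <- sprintf("B%02d", seq_len(n_pm))

    A <- setNames(vapply(pm_a, function(p) random_dna(L), character(1)), pm_a)

    # genes round-robin over A pseudomolecules; mirrored to B
    gene_pm <- rep(seq_len(n_pm), length.out = config$n_genes)
    feats <- list()
    writes <- list()  # per A-pm list of (at, seq)
    for (i in seq_len(n_pm)) {
      k <- sum(gene_pm == i)
      if (k == 0) next
      sts <- replicate(k, sample_gene_structure(), simplify = FALSE)
      spans <- vapply(sts, `[[`, numeric(1), "span")
      slack <- L - 200L - sum(spans) - (k + 1L) * 100L
      if (slack < 0)
        stop(sprintf(
          "gene models do not fit: pseudomolecule length %d cannot hold %d genes spanning %d bases plus minimum gaps",
          L, k, sum(spans)))
      extras <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1L)))
      cursor <- 101L
      for (j in seq_len(k)) {
        cursor <- cursor + 100L + extras[j]
        gid <- sprintf("gene%s_%03d", pm_a[i], j)
        lay <- layout_gene(pm_a[i], gid, cursor, sts[[j]])
        cds_seq <- sample_coding_sequence(sts[[j]]$cds_len)
        e1 <- sts[[j]]$e1
        if (sts[[j]]$strand == "+") {
          seg1 <- substr(cds_seq, 1, e1)
          seg2 <- substr(cds_seq, e1 + 1, sts[[j]]$cds_len)
        } else {
          seg1 <- reverse_complement(substr(cds_seq, 1, e1))
          seg2 <- reverse_complement(substr(cds_seq, e1 + 1, sts[[j]]$cds_len))
        }
        writes[[length(writes) + 1L]] <-
          list(pm = i, at = lay$first_cds[1], seq = seg1)
        writes[[length(writes) + 1L]] <-
          list(pm = i, at = lay$second_cds[1], seq = seg2)
        feats[[length(feats) + 1L]] <- lay$features
        cursor <- lay$gend + 1L
      }
    }
    for (w in writes) A[w$pm] <- str_overwrite(A[[w$pm]], w$at, w$seq)

    annotation_a <- if (length(feats)) do.call(rbind, feats) else
      data.frame(seqid = character(), type = character(), start = integer(),
                 end = integer(), strand = character(), gene_id = character(),
                 transcript_id = character(), stringsAsFactors = FALSE)
    annotation_b <- annotation_a
    if (nrow(annotation_b)) {
      annotation_b$seqid <- sub("^A", "B", annotation_b$seqid)
      annotation_b$gene_id <- sub("geneA", "geneB", annotation_b$gene_id)
      annotation_b$transcript_id <- sub("geneA", "geneB", annotation_b$transcript_id)
    }
    annotation <- rbind(annotation_a, annotation_b)
    rownames(annotation) <- NULL

    # B = A mutated at uniformly sampled sites
    B <- setNames(character(n_pm), pm_b)
    for (i in seq_len(n_pm)) {
      s <- strsplit(A[[i]], "", fixed = TRUE)[[1]]
      mut <- which(runif(L) < config$homeolog_divergence)
      if (length(mut)) {
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(DNA_BASES, b), 1),
                         character(1), USE.NAMES = FALSE)
      }
      B[i] <- paste(s, collapse = "")
    }

    B <- repair_reading_frames(B, A, annotation_b, pm_b, pm_a)

    list(genomes = list(A = A, B = B), annotation = annotation,
         config = config)
  })
}

# Revert divergence mutations that break a reading frame on the mutated copy:
# premature stops, a damaged initiator ATG, or a destroyed terminal stop.
repair_reading_frames <- function(B, A, annotation_b, pm_b, pm_a) {
  if (!nrow(annotation_b)) return(B)
  cds <- annotation_b[annotation_b$type == "CDS", ]
  for (tid in unique(cds$transcript_id)) {
    blocks <- cds[cds$transcript_id == tid, ]
    seqid <- blocks$seqid[1]
    i <- match(seqid, pm_b)
    gpos <- cds_genomic_positions(blocks, blocks$strand[1])
    bchars <- strsplit(B[[i]], "", fixed = TRUE)[[1]]
    achars <- strsplit(A[[pm_a[i]]], "", fixed = TRUE)[[1]]
    get_cds <- function(chars) {
      s <- chars[gpos]
      if (blocks$strand[1] == "-") s <- chartr("ACGT", "TGCA", s)
      s
    }
    repeat {
      s <- get_cds(bchars)
      n_codons <- length(s) / 3L
      codons <- vapply(seq_len(n_codons), function(k)
        paste(s[(3 * k - 2):(3 * k)], collapse = ""), character(1))
      bad <- integer(0)
      if (codons[1] != "ATG") bad <- c(bad, 1L)
      prem <- which(codons[-c(1L, n_codons)] %in% STOP_CODONS) + 1L
      bad <- c(bad, prem)
      if (!(codons[n_codons] %in% STOP_CODONS)) bad <- c(bad, n_codons)
      if (!length(bad)) break
      for (k in bad) {
        idx <- gpos[(3 * k - 2):(3 * k)]
        bchars[idx] <- achars[idx]
      }
    }
    B[i] <- paste(bchars, collapse = "")
  }
  B
}

# Merged [start,end] windows within `window` of any gene on one pseudomolecule,
# clipped so a 35-base flank fits on each side.
near_gene_intervals <- function(annotation, seqid, L, window = 10000L,
                                margin = 35L) {
  genes <- annotation[annotation$type == "gene" & annotation$seqid == seqid, ]
  if (!nrow(genes)) return(NULL)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(margin + 1L, genes$start - window),
    end = pmin(L - margin, genes$end + window)))
  cbind(start = IRanges::start(ir), end = IRanges::end(ir))
}

species_pool <- function(subgenome) {
  if (subgenome == "A") {
    list(sp = c("A. hypogaea", "A. duranensis", "A. cardenasii", "A. stenosperma"),
         pr = c(0.77, 0.10, 0.07, 0.06))
  } else {
    list(sp = c("A. hypogaea", "A. ipaensis", "A. magna", "A. batizocoi"),
         pr = c(0.77, 0.08, 0.08, 0.07))
  }
}

#' Generate a candidate-SNP pool with planted artifact classes
#'
#' Emits `n_true_snps` genuine biallelic SNPs within 10 kb of genes,
#' `n_homeolog_artifacts` candidates whose alternate allele equals the
#' homeologous subgenome base (at sites whose 71-base context stays above the
#' homeolog filter's identity threshold, so the artifact is detectable by
#' construction), `n_duplicated_flank_snps` candidates whose probe context is
#' copied (whole, or as a 60-base core, forward or reverse-complemented) into
#' an intergenic region of the same subgenome, and `n_multiallelic` loci with
#' two alternate alleles. True SNPs are constructed so their alternate allele
#' never equals the homeologous base, keeping truth labels and filter flags in
#' exact correspondence.
#'
#' Duplicated-flank planting edits the reference sequence, so the (possibly
#' modified) genomes are returned alongside the candidate table and must be
#' used for all downstream searches.
#'
#' @param genomes `genomes` element of [generate_genomes()] output.
#' @param annotation feature data frame from [generate_genomes()].
#' @param config the same [sim_config()].
#' @return list with `candidates` (data frame), `truth` (labels and planted
#'   ids) and `genomes` (with planted duplications).
#' @export
generate_candidates <- function(genomes, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "candidates"), {
    L <- config$pseudomolecule_length
    pm_a <- names(genomes$A)
    pm_b <- names(genomes$B)
    n_pm <- length(pm_a)
    all_pm <- c(pm_a, pm_b)
    used <- lapply(setNames(all_pm, all_pm), function(p) logical(L))
    # regions whose sequence was duplicated or overwritten; no candidate may
    # sit near them on either the pseudomolecule or its homeologous mirror,
    # or its cross-subgenome placements would change
    blocked <- lapply(setNames(all_pm, all_pm), function(p) logical(L))
    mirror_pm <- setNames(c(pm_b, pm_a), all_pm)
    dilate <- function(x, w) {
      idx <- which(x)
      for (i in idx) x[max(1L, i - w):min(L, i + w)] <- TRUE
      x
    }

    near <- lapply(setNames(all_pm, all_pm), function(p)
      near_gene_intervals(annotation, p, L))

    get_seq <- function(sub, i) if (sub == "A") genomes$A[[i]] else genomes$B[[i]]

    mm_window <- function(i) {
      # mismatch count between subgenomes in every 71-base window, centred
      a <- utf8ToInt(genomes$A[[i]])
      b <- utf8ToInt(genomes$B[[i]])
      d <- as.integer(a != b)
      cs <- c(0L, cumsum(d))
      p <- seq_len(L)
      lo <- pmax(p - 36L, 0L)
      hi <- pmin(p + 35L, L)
      list(diff = d == 1L, wmm = cs[hi + 1L] - cs[lo + 1L])
    }

    take_positions <- function(sub, n, what, extra_ok = NULL) {
      # distribute n positions over this subgenome's pseudomolecules
      if (n == 0) return(NULL)
      out <- vector("list", n_pm)
      counts <- as.vector(stats::rmultinom(1, n, rep(1, n_pm)))
      for (i in seq_len(n_pm)) {
        if (counts[i] == 0) next
        p <- if (sub == "A") pm_a[i] else pm_b[i]
        iv <- near[[p]]
        if (is.null(iv)) stop(sprintf("no genes on %s to place candidates near", p))
        widths <- unlist(lapply(seq_len(nrow(iv)), function(r) iv[r, 1]:iv[r, 2]))
        ok <- !used[[p]][widths] & !blocked[[p]][widths]
        if (!is.null(extra_ok)) ok <- ok & extra_ok[[i]][widths]
        pool <- widths[ok]
        if (length(pool) < counts[i])
          stop(sprintf("requested %s count exceeds available placements on %s",
                       what, p))
        pos <- sample(pool, counts[i])
        used[[p]][pos] <<- TRUE
        out[[i]] <- data.frame(subgenome = sub, pm_index = i,
                               pseudomolecule = p, position = pos,
                               stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }

    base_at <- function(sub, i, pos) substr(get_seq(sub, i), pos, pos)
    flanks_at <- function(sub, i, pos) {
      s <- get_seq(sub, i)
      c(substr(s, pos - 35L, pos - 1L), substr(s, pos + 1L, pos + 35L))
    }

    make_rows <- function(locs, kind) {
      if (is.null(locs)) return(NULL)
      n <- nrow(locs)
      rows <- vector("list", n)
      for (r in seq_len(n)) {
        sub <- locs$subgenome[r]; i <- locs$pm_index[r]; pos <- locs$position[r]
        other <- if (sub == "A") "B" else "A"
        ref <- base_at(sub, i, pos)
        cross <- base_at(other, i, pos)
        fl <- flanks_at(sub, i, pos)
        if (kind == "homeolog_artifact") {
          alt <- cross
          multi <- FALSE
        } else if (kind == "multiallelic") {
          alts <- sample(setdiff(DNA_BASES, ref), 2)
          alt <- paste(alts, collapse = ",")
          multi <- TRUE
        } else {
          choices <- setdiff(DNA_BASES, unique(c(ref, cross)))
          alt <- if (length(choices) == 1) choices else sample(choices, 1)
          multi <- FALSE
        }
        sp <- species_pool(sub)
        rows[[r]] <- data.frame(
          subgenome = sub, pseudomolecule = locs$pseudomolecule[r],
          position = pos, ref_allele = ref, alt_allele = alt,
          multiallelic = multi,
          source_species = sample(sp$sp, 1, prob = sp$pr),
          flank_left = fl[1], flank_right = fl[2],
          trait_linked = FALSE, label = kind, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }

    # homeolog artifacts need diverged sites with conserved 71-base context
    max_mm <- 4L  # floor(71 * (1 - 0.94)): context still clears 94% identity
    homeo_rows <- NULL
    if (config$n_homeolog_artifacts > 0) {
      masks <- lapply(seq_len(n_pm), mm_window)
      sub <- sample(c("A", "B"), config$n_homeolog_artifacts, replace = TRUE)
      homeo_rows <- do.call(rbind, lapply(c("A", "B"), function(s) {
        n_s <- sum(sub == s)
        if (n_s == 0) return(NULL)
        ok <- lapply(masks, function(m) m$diff & m$wmm <= max_mm)
        locs <- take_positions(s, n_s, "homeolog artifact", extra_ok = ok)
        make_rows(locs, "homeolog_artifact")
      }))
    }

    # most true SNPs fall inside gene bodies (resequencing against
    # gene-anchored references plus RNA-seq), the rest in the 10-kb flanks
    genic <- lapply(seq_len(n_pm), function(i) {
      m <- logical(L)
      gg <- annotation[annotation$type == "gene" &
                         annotation$seqid %in% c(pm_a[i], pm_b[i]), ]
      for (r in seq_len(nrow(gg))) m[gg$start[r]:gg$end[r]] <- TRUE
      m
    })
    true_sub <- sample(c("A", "B"), config$n_true_snps, replace = TRUE,
                       prob = c(0.55, 0.45))
    true_rows <- do.call(rbind, lapply(c("A", "B"), function(s) {
      n_s <- sum(true_sub == s)
      if (n_s == 0) return(NULL)
      n_genic <- round(0.6 * n_s)
      rbind(
        if (n_genic > 0)
          make_rows(take_positions(s, n_genic, "true SNP", extra_ok = genic),
                    "true_variant"),
        if (n_s - n_genic > 0)
          make_rows(take_positions(s, n_s - n_genic, "true SNP"),
                    "true_variant"))
    }))

    dup_rows <- NULL
    if (config$n_duplicated_flank_snps > 0) {
      dsub <- sample(c("A", "B"), config$n_duplicated_flank_snps, replace = TRUE)
      dup_rows <- do.call(rbind, lapply(c("A", "B"), function(s) {
        n_s <- sum(dsub == s)
        if (n_s == 0) return(NULL)
        # the copied source region must keep a full context length clear of
        # every other candidate, on its own pseudomolecule (a neighbour's
        # context would partially match the copy) and on the homeologous
        # mirror (a neighbour's cross-subgenome counterpart would)
        ok <- lapply(seq_len(n_pm), function(i) {
          p <- if (s == "A") pm_a[i] else pm_b[i]
          q <- mirror_pm[[p]]
          !dilate(used[[p]] | blocked[[p]] | used[[q]] | blocked[[q]], 71L)
        })
        locs <- take_positions(s, n_s, "duplicated-flank SNP", extra_ok = ok)
        for (r in seq_len(nrow(locs))) {
          p <- locs$pseudomolecule[r]
          q <- mirror_pm[[p]]
          pos <- locs$position[r]
          win <- max(1L, pos - 71L):min(L, pos + 71L)
          blocked[[p]][win] <<- TRUE
          blocked[[q]][win] <<- TRUE
        }
        make_rows(locs, "duplicated_flank")
      }))
      # plant the copies in gene-free gaps of the same subgenome, clear of
      # every existing candidate's probe context
      gene_tab <- annotation[annotation$type == "gene", , drop = FALSE]
      for (r in seq_len(nrow(dup_rows))) {
        sub <- dup_rows$subgenome[r]
        ctx <- paste0(dup_rows$flank_left[r], dup_rows$ref_allele[r],
                      dup_rows$flank_right[r])
        if (runif(1) < 0.5) ctx <- substr(ctx, 7, 66)       # 60-base core
        if (runif(1) < 0.5) ctx <- reverse_complement(ctx)  # either orientation
        w <- nchar(ctx)
        placed <- FALSE
        for (attempt in seq_len(500)) {
          i <- sample(n_pm, 1)
          p <- if (sub == "A") pm_a[i] else pm_b[i]
          at <- sample(seq(101L, L - 100L - w), 1)
          q <- mirror_pm[[p]]
          gg <- gene_tab[gene_tab$seqid %in% c(p, q), , drop = FALSE]
          in_gene <- nrow(gg) > 0 &&
            any(gg$start - 10L <= (at + w - 1L) & gg$end + 10L >= at)
          lo <- max(1L, at - 36L); hi <- min(L, at + w + 35L)
          if (in_gene || any(used[[p]][lo:hi] | blocked[[p]][lo:hi] |
                             used[[q]][lo:hi] | blocked[[q]][lo:hi])) next
          if (sub == "A") genomes$A[[i]] <- str_overwrite(genomes$A[[i]], at, ctx)
          else genomes$B[[i]] <- str_overwrite(genomes$B[[i]], at, ctx)
          blocked[[p]][lo:hi] <- TRUE  # keep later candidates off the copy
          blocked[[q]][lo:hi] <- TRUE  # and off its homeologous mirror
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place a duplicated-flank copy clear of genes and existing candidates; reduce n_duplicated_flank_snps or enlarge pseudomolecules")
      }
    }

    multi_rows <- NULL
    if (config$n_multiallelic > 0) {
      # placed at non-diverged sites so the homeolog filter can never match
      # one of the sampled alternate alleles to the cross-subgenome base
      same <- lapply(seq_len(n_pm), function(i) {
        a <- utf8ToInt(genomes$A[[i]]); b <- utf8ToInt(genomes$B[[i]])
        a == b
      })
      msub <- sample(c("A", "B"), config$n_multiallelic, replace = TRUE)
      multi_rows <- do.call(rbind, lapply(c("A", "B"), function(s) {
        n_s <- sum(msub == s)
        if (n_s == 0) return(NULL)
        locs <- take_positions(s, n_s, "multiallelic locus", extra_ok = same)
        make_rows(locs, "multiallelic")
      }))
    }

    cand <- rbind(true_rows, homeo_rows, dup_rows, multi_rows)
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    cand$snp_id <- sprintf("SNP%06d", seq_len(nrow(cand)))
    rownames(cand) <- NULL
    if (config$n_trait_linked > 0) {
      tl <- sample(which(cand$label == "true_variant"), config$n_trait_linked)
      cand$trait_linked[tl] <- TRUE
    }
    truth <- list(
      labels = data.frame(snp_id = cand$snp_id, label = cand$label,
                          stringsAsFactors = FALSE)
    )
    cand$label <- NULL
    cand <- cand[, c("snp_id", "subgenome", "pseudomolecule", "position",
                     "ref_allele", "alt_allele", "multiallelic",
                     "source_species", "flank_left", "flank_right",
                     "trait_linked")]
    list(candidates = cand, truth = truth, genomes = genomes)
  })
}

#' Generate a structured genotype panel over an array manifest
#'
#' Draws a panel of wild, fastigiata and hypogaea samples. Background SNPs
#' share one per-SNP alternate-allele frequency between the two cultivated
#' categories (Beta(0.5, 2.5), giving the low-MAF spectrum typical of a
#' selfing crop); the wild category's frequency is that background mixed with
#' an independent uniform draw (`wild_divergence`), so the wild group is both
#' more polymorphic and genuinely separated. Planted subspecies-specific SNPs
#' get alternate-allele frequency in [0.92, 1] in their target category and
#' [0, 0.08] elsewhere; a `shared_wild_fraction` of the hypogaea-specific set
#' is also high-frequency in the wild group. Genotypes are drawn per category
#' under inbreeding coefficient `inbreeding`; missing calls are inserted at
#' `missing_rate`.
#'
#' @param manifest data frame with at least `snp_id` (an array manifest).
#' @param config a [sim_config()].
#' @param freq_override optional function(freqs) receiving and returning the
#'   category frequency list (`fastigiata`, `hypogaea`, `wild`, each a vector
#'   over SNPs) before genotypes are drawn; used to set up extreme planted
#'   scenarios in tests.
#' @return list with `panel` (a [genotype_matrix()]) and `truth` (planted
#'   specific SNP ids per category, wild-shared ids, cluster assignment).
#' @export
generate_panel <- function(manifest, config, freq_override = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(manifest)) stop("manifest is empty")
  if (2L * config$n_planted_specific > nrow(manifest))
    stop("n_planted_specific exceeds manifest size")
  with_seed(derive_seed(config$seed, "panel"), {
    m <- nrow(manifest)
    ids <- manifest$snp_id
    p_bg <- stats::rbeta(m, 0.5, 2.5)
    u <- runif(m)
    freqs <- list(
      fastigiata = p_bg,
      hypogaea = p_bg,
      wild = (1 - config$wild_divergence) * p_bg + config$wild_divergence * u
    )
    planted <- list(fastigiata = character(0), hypogaea = character(0))
    shared_wild <- character(0)
    if (config$n_planted_specific > 0) {
      sel <- sample(m, 2L * config$n_planted_specific)
      fi <- sel[seq_len(config$n_planted_specific)]
      hi <- sel[-seq_len(config$n_planted_specific)]
      planted$fastigiata <- ids[fi]
      planted$hypogaea <- ids[hi]
      freqs$fastigiata[fi] <- runif(length(fi), 0.92, 1)
      freqs$hypogaea[fi] <- runif(length(fi), 0, 0.08)
      freqs$wild[fi] <- runif(length(fi), 0, 0.08)
      freqs$hypogaea[hi] <- runif(length(hi), 0.92, 1)
      freqs$fastigiata[hi] <- runif(length(hi), 0, 0.08)
      n_shared <- round(config$shared_wild_fraction * length(hi))
      sw <- head(hi, n_shared)
      freqs$wild[hi] <- runif(length(hi), 0, 0.08)
      if (n_shared > 0) {
        freqs$wild[sw] <- runif(n_shared, 0.92, 1)
        shared_wild <- ids[sw]
      }
    }
    sub_snps <- character(0)
    if (config$n_sublineage_snps > 0 && config$n_hypogaea >= 2) {
      pool <- setdiff(seq_len(m), unlist(lapply(planted, match, ids)))
      si <- sample(pool, min(config$n_sublineage_snps, length(pool)))
      freqs$hypogaea_sublineage <- freqs$hypogaea
      freqs$hypogaea_sublineage[si] <- runif(length(si), 0.9, 1)
      freqs$hypogaea[si] <- runif(length(si), 0, 0.1)
      sub_snps <- ids[si]
    }
    if (!is.null(freq_override)) freqs <- freq_override(freqs)
    hypo_sub_freq <- freqs$hypogaea_sublineage
    if (is.null(hypo_sub_freq)) hypo_sub_freq <- freqs$hypogaea

    draw_category <- function(n, pv) {
      if (n == 0) return(NULL)
      Fc <- config$inbreeding
      p0 <- (1 - pv)^2 + Fc * pv * (1 - pv)
      p1 <- 2 * pv * (1 - pv) * (1 - Fc)
      uu <- matrix(runif(n * length(pv)), nrow = n)
      g <- (uu > matrix(p0, n, length(pv), byrow = TRUE)) +
        (uu > matrix(p0 + p1, n, length(pv), byrow = TRUE))
      storage.mode(g) <- "integer"
      g
    }

    n_hyp_main <- ceiling(config$n_hypogaea / 2)
    n_hyp_sub <- config$n_hypogaea - n_hyp_main
    calls <- rbind(
      draw_category(config$n_wild, freqs$wild),
      draw_category(config$n_fastigiata, freqs$fastigiata),
      draw_category(n_hyp_main, freqs$hypogaea),
      draw_category(n_hyp_sub, hypo_sub_freq)
    )
    if (config$missing_rate > 0) {
      miss <- matrix(runif(length(calls)) < config$missing_rate,
                     nrow = nrow(calls))
      calls[miss] <- -1L
    }
    wild_sp <- c("A. duranensis", "A. ipaensis", "A. stenosperma",
                 "A. cardenasii", "A. magna", "A. batizocoi")
    samples <- data.frame(
      sample = c(sprintf("WILD%03d", seq_len(config$n_wild)),
                 sprintf("FAST%03d", seq_len(config$n_fastigiata)),
                 sprintf("HYPO%03d", seq_len(config$n_hypogaea))),
      species = c(sample(wild_sp, config$n_wild, replace = TRUE),
                  rep("A. hypogaea", config$n_fastigiata + config$n_hypogaea)),
      ploidy = c(rep("diploid", config$n_wild),
                 rep("tetraploid", config$n_fastigiata + config$n_hypogaea)),
      category = c(rep("wild", config$n_wild),
                   rep("fastigiata", config$n_fastigiata),
                   rep("hypogaea", config$n_hypogaea)),
      stringsAsFactors = FALSE
    )
    rownames(calls) <- samples$sample
    colnames(calls) <- ids
    panel <- genotype_matrix(calls, samples, manifest)
    sublineage <- setNames(rep(NA_character_, nrow(samples)), samples$sample)
    hyp_ids <- samples$sample[samples$category == "hypogaea"]
    if (length(hyp_ids)) {
      sublineage[hyp_ids] <- rep(c("hypogaea_main", "hypogaea_sub"),
                                 c(n_hyp_main, n_hyp_sub))
    }
    truth <- list(planted_specific = planted, shared_with_wild = shared_wild,
                  sublineage_snps = sub_snps,
                  clusters = setNames(samples$category, samples$sample),
                  sublineage = sublineage,
                  frequencies = freqs)
    list(panel = panel, truth = truth)
  })
}
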