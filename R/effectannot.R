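EFFECT_SEVERITY <- c(
  stop_gained = 1L, stop_lost = 2L, start_lost = 3L,
  non_synonymous_start = 4L, non_synonymous_stop = 5L,
  non_synonymous_coding = 6L, synonymous_coding = 7L,
  UTR_5_prime = 8L, UTR_3_prime = 9L, intron = 10L, intergenic = 11L,
  others = 12L
)

# Per-transcript structures from a feature data frame, for repeated lookups.
build_transcript_models <- function(annotation) {
  mrna <- annotation[annotation$type == "mRNA", , drop = FALSE]
  out <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$transcript_id[i]
    sub <- annotation[!is.na(annotation$transcript_id) &
                        annotation$transcript_id == tid, , drop = FALSE]
    blocks <- function(tp) {
      b <- sub[sub$type == tp, c("start", "end"), drop = FALSE]
      b[order(b$start), , drop = FALSE]
    }
    list(transcript_id = tid, gene_id = mrna$gene_id[i],
         seqid = mrna$seqid[i], strand = mrna$strand[i],
         start = mrna$start[i], end = mrna$end[i],
         cds = blocks("CDS"), exon = blocks("exon"),
         utr5 = blocks("five_prime_UTR"), utr3 = blocks("three_prime_UTR"))
  })
  names(out) <- vapply(out, `[[`, character(1), "transcript_id")
  out
}

in_blocks <- function(pos, blocks) {
  nrow(blocks) > 0 && any(pos >= blocks$start & pos <= blocks$end)
}

# Full CDS sequence of a transcript in translation order.
extract_cds <- function(model, genome_seq) {
  segs <- vapply(seq_len(nrow(model$cds)), function(i)
    substr(genome_seq, model$cds$start[i], model$cds$end[i]), character(1))
  s <- paste(segs, collapse = "")
  if (model$strand == "-") s <- reverse_complement(s)
  s
}

translate_codon <- function(codon) {
  Biostrings::GENETIC_CODE[[codon]]
}

# Classify one SNP against one transcript; returns list(category, codon_change).
classify_in_transcript <- function(pos, ref, alt, model, genome_seq) {
  if (!in_blocks(pos, model$exon)) {
    if (pos >= model$start && pos <= model$end)
      return(list(category = "intron", codon_change = NA_character_))
    return(NULL)
  }
  if (in_blocks(pos, model$utr5))
    return(list(category = "UTR_5_prime", codon_change = NA_character_))
  if (in_blocks(pos, model$utr3))
    return(list(category = "UTR_3_prime", codon_change = NA_character_))
  if (!in_blocks(pos, model$cds))
    return(list(category = "others", codon_change = NA_character_))

  gpos <- cds_genomic_positions(model$cds, model$strand)
  cds_pos <- match(pos, gpos)
  cds_seq <- extract_cds(model, genome_seq)
  if (nchar(cds_seq) %% 3L != 0L)
    return(list(category = "others", codon_change = NA_character_))
  n_codons <- nchar(cds_seq) / 3L
  ref_t <- ref; alt_t <- alt
  if (model$strand == "-") {
    ref_t <- complement_base(ref)
    alt_t <- complement_base(alt)
  }
  if (substr(cds_seq, cds_pos, cds_pos) != ref_t)
    return(list(category = "others", codon_change = NA_character_))
  ci <- (cds_pos - 1L) %/% 3L + 1L
  off <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(cds_seq, 3L * ci - 2L, 3L * ci)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_t
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  change <- paste0(ref_codon, "/", alt_codon)
  category <-
    if (ref_aa == alt_aa) "synonymous_coding"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else if (ci == 1L) "start_lost"
    else if (ci == 2L) "non_synonymous_start"
    else if (ci == n_codons - 1L) "non_synonymous_stop"
    else "non_synonymous_coding"
  list(category = category, codon_change = change)
}

#' Classify SNP effects against gene models
#'
#' Locates each biallelic SNP relative to the annotated transcripts
#' (strand-aware) and assigns one category. Inside a CDS the reference and
#' alternate codons are translated with the standard genetic code:
#' an unchanged amino acid is `synonymous_coding`; an alternate stop is
#' `stop_gained`; loss of the terminal stop is `stop_lost`; any change in the
#' initiator codon is `start_lost`; amino-acid changes in the codon adjacent
#' to the start or stop are `non_synonymous_start` / `non_synonymous_stop`
#' (a positional interpretation — the array literature leaves these
#' undefined); anything else is `non_synonymous_coding`. SNPs in introns and
#' UTRs get the corresponding category, SNPs in no transcript are
#' `intergenic`, and unclassifiable cases (e.g. a CDS whose length is not a
#' multiple of three, or a reference mismatch) fall into `others`. With
#' overlapping transcripts the most severe category wins.
#'
#' @param snps data frame with `snp_id`, `pseudomolecule`, `position`,
#'   `ref_allele`, `alt_allele`.
#' @param annotation feature data frame.
#' @param genomes list with subgenome references `A` and `B`.
#' @return data frame `snp_id`, `category`, `gene_id`, `codon_change`.
#' @export
classify_effect <- function(snps, annotation, genomes) {
  models <- build_transcript_models(annotation)
  by_seq <- split(seq_along(models),
                  vapply(models, `[[`, character(1), "seqid"))
  all_seqs <- c(genomes$A, genomes$B)
  n <- nrow(snps)
  category <- character(n)
  gene_id <- rep(NA_character_, n)
  codon_change <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- snps$pseudomolecule[i]
    pos <- snps$position[i]
    gseq <- all_seqs[[p]]
    if (is.null(gseq)) stop(sprintf("unknown pseudomolecule '%s'", p))
    if (pos < 1L || pos > nchar(gseq))
      stop(sprintf("SNP %s at position %d lies beyond pseudomolecule %s",
                   snps$snp_id[i], pos, p))
    hits <- list()
    for (mi in by_seq[[p]]) {
      m <- models[[mi]]
      if (pos < m$start || pos > m$end) next
      cl <- classify_in_transcript(pos, snps$ref_allele[i],
                                   substr(snps$alt_allele[i], 1, 1), m, gseq)
      if (!is.null(cl)) {
        cl$gene_id <- m$gene_id
        hits[[length(hits) + 1L]] <- cl
      }
    }
    if (!length(hits)) {
      category[i] <- "intergenic"
    } else {
      sev <- vapply(hits, function(h) EFFECT_SEVERITY[[h$category]], integer(1))
      best <- hits[[which.min(sev)]]
      category[i] <- best$category
      gene_id[i] <- best$gene_id
      codon_change[i] <- best$codon_change
    }
  }
  data.frame(snp_id = snps$snp_id, category = category, gene_id = gene_id,
             codon_change = codon_change, stringsAsFactors = FALSE)
}

#' Tabulate effect categories by subgenome
#'
#' Produces the category-by-subgenome count table (categories in their
#' conventional reporting order, a `both` column summing the subgenomes, and
#' a `Total` row).
#'
#' @param annotations output of [classify_effect()].
#' @param subgenome character vector ("A"/"B") aligned to `annotations` rows.
#' @return data frame with columns `category`, `A`, `B`, `both`.
#' @export
summarize_annotation <- function(annotations, subgenome) {
  tab <- table(factor(annotations$category, levels = EFFECT_CATEGORIES),
               factor(subgenome, levels = c("A", "B")))
  out <- data.frame(category = EFFECT_CATEGORIES,
                    A = as.integer(tab[, "A"]),
                    B = as.integer(tab[, "B"]),
                    stringsAsFactors = FALSE)
  out$both <- out$A + out$B
  rbind(out, data.frame(category = "Total", A = sum(out$A), B = sum(out$B),
                        both = sum(out$both), stringsAsFactors = FALSE))
}
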