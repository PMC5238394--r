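# Readers and writers for the plain-text formats the workflow exchanges:
# FASTA, GFF3, VCF 4.2 + flank sidecar, genotype TSV, Newick, JSON, YAML.
# All writers emit byte-stable output under fixed inputs.

#' Write subgenome references as FASTA
#'
#' @param genomes list with named character vectors `A` and `B` (or a single
#'   named character vector).
#' @param path output file; sequences are wrapped at 60 columns.
#' @export
write_fasta <- function(genomes, path) {
  seqs <- if (is.list(genomes)) c(genomes$A, genomes$B) else genomes
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write gene-model features as GFF3
#'
#' @param annotation feature data frame (`seqid`, `type`, `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`).
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqid,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$source <- "allosnp"
  S4Vectors::mcols(gr)$type <- annotation$type
  id <- ifelse(annotation$type == "gene", annotation$gene_id,
               ifelse(annotation$type == "mRNA", annotation$transcript_id,
                      NA_character_))
  parent <- ifelse(annotation$type == "gene", NA_character_,
                   ifelse(annotation$type == "mRNA", annotation$gene_id,
                          annotation$transcript_id))
  S4Vectors::mcols(gr)$ID <- id
  S4Vectors::mcols(gr)$Parent <- parent
  # CDS phase from cumulative coding length in transcript order
  phase <- rep(NA_integer_, nrow(annotation))
  cds_rows <- which(annotation$type == "CDS")
  for (tid in unique(annotation$transcript_id[cds_rows])) {
    rows <- cds_rows[annotation$transcript_id[cds_rows] == tid]
    ord <- order(annotation$start[rows],
                 decreasing = annotation$strand[rows[1]] == "-")
    lens <- annotation$end[rows][ord] - annotation$start[rows][ord] + 1L
    phase[rows[ord]] <- as.integer((3L - cumsum(c(0L, lens))[seq_along(lens)] %% 3L) %% 3L)
  }
  S4Vectors::mcols(gr)$phase <- phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into the package's feature data frame
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS/UTR features linked by
#'   ID/Parent attributes.
#' @return feature data frame.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  id <- as.character(S4Vectors::mcols(gr)$ID)
  parent <- S4Vectors::mcols(gr)$Parent
  parent <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  tid2gene <- setNames(parent[df$type == "mRNA"], id[df$type == "mRNA"])
  df$gene_id <- ifelse(df$type == "gene", id,
                       ifelse(df$type == "mRNA", parent,
                              unname(tid2gene[parent])))
  df$transcript_id <- ifelse(df$type == "gene", NA_character_,
                             ifelse(df$type == "mRNA", id, parent))
  df
}

#' Write a candidate-SNP table as VCF 4.2 plus a flank sidecar TSV
#'
#' The VCF carries CHROM/POS/ID/REF/ALT (multi-allelic loci as multi-ALT
#' rows); flanks, source species and flags travel in the sidecar, keyed by
#' snp_id.
#'
#' @param candidates candidate data frame.
#' @param vcf_path,tsv_path output paths.
#' @export
write_candidates <- function(candidates, vcf_path, tsv_path) {
  # records previously expanded from one multi-ALT locus are regrouped so
  # that read -> write -> read is lossless
  key <- paste(candidates$snp_id, candidates$pseudomolecule,
               candidates$position, candidates$ref_allele, sep = "\r")
  first <- !duplicated(key)
  alt <- vapply(split(candidates$alt_allele, factor(key, levels = key[first])),
                function(a) paste(unique(unlist(strsplit(a, ",", TRUE))),
                                  collapse = ","), character(1))
  rows <- candidates[first, , drop = FALSE]
  rows$alt_allele <- unname(alt)
  con <- file(vcf_path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=allosnp",
               paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                   "QUAL", "FILTER", "INFO"), collapse = "\t"))),
             con)
  body <- paste(rows$pseudomolecule, rows$position, rows$snp_id,
                rows$ref_allele, rows$alt_allele, ".", ".",
                paste0("SUBGENOME=", rows$subgenome), sep = "\t")
  writeLines(body, con)
  close(con)
  sidecar <- rows[, c("snp_id", "flank_left", "flank_right",
                      "source_species", "trait_linked")]
  write.table(sidecar, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Read a candidate-SNP VCF plus flank sidecar
#'
#' Multi-ALT rows expand to one record per alternate allele, each flagged
#' multiallelic. Malformed rows are reported with their line number.
#'
#' @param vcf_path VCF 4.2 file.
#' @param tsv_path flank sidecar TSV (keyed by snp_id); optional.
#' @return candidate data frame.
#' @export
read_candidates <- function(vcf_path, tsv_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fx$POS))
  if (any(is.na(pos)))
    stop(sprintf("malformed VCF row (bad POS) at data line %d",
                 which(is.na(pos))[1]))
  sub <- ifelse(grepl("SUBGENOME=B", fx$INFO %||% ""), "B",
                substr(fx$CHROM, 1, 1))
  rows <- lapply(seq_len(nrow(fx)), function(i) {
    alts <- strsplit(fx$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(snp_id = fx$ID[i], subgenome = sub[i],
               pseudomolecule = fx$CHROM[i], position = pos[i],
               ref_allele = fx$REF[i], alt_allele = alts,
               multiallelic = length(alts) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(tsv_path)) {
    sidecar <- read.delim(tsv_path, stringsAsFactors = FALSE)
    m <- match(out$snp_id, sidecar$snp_id)
    out$flank_left <- sidecar$flank_left[m]
    out$flank_right <- sidecar$flank_right[m]
    out$source_species <- sidecar$source_species[m]
    out$trait_linked <- sidecar$trait_linked[m]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype matrix as TSV
#'
#' Metadata columns (sample, species, ploidy, category) lead; one column per
#' snp_id follows; missing calls are written as NA.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(gm, path) {
  calls <- gm$calls
  calls[calls == -1L] <- NA_integer_
  df <- cbind(gm$samples[, c("sample", "species", "ploidy", "category")],
              as.data.frame(calls, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype TSV into a genotype matrix
#'
#' @param path TSV with metadata columns (sample, species, ploidy, category)
#'   then one column per snp_id; calls coded 0/1/2 with NA for missing.
#' @param snps optional SNP table; defaults to a minimal table of the snp_id
#'   columns found.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, snps = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1) stop("ragged rows in genotype TSV")
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("sample", "species", "ploidy", "category")
  if (!all(meta_cols %in% names(df)))
    stop("genotype TSV must lead with sample, species, ploidy, category")
  snp_cols <- names(df)[!names(df) %in% meta_cols]
  if (anyDuplicated(snp_cols)) stop("duplicate snp_id column in genotype TSV")
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in genotype TSV")
  calls <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(NA_integer_, 0L, 1L, 2L))
  if (any(bad)) stop("unknown genotype codes in TSV (expected 0/1/2/NA)")
  calls[is.na(calls)] <- -1L
  rownames(calls) <- df$sample
  if (is.null(snps)) snps <- data.frame(snp_id = snp_cols,
                                        stringsAsFactors = FALSE)
  genotype_matrix(calls, df[, meta_cols], snps)
}

#' Write truth labels as JSON
#' @param truth truth object from the generators.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read truth labels from JSON
#' @param path JSON file written by [write_truth()].
#' @return truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a tree in Newick format
#' @param tree a `phylo` tree.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

RUN_CONFIG_DEFAULTS <- list(
  filter_window = 10000L,
  filter_identity = 0.94,
  filter_min_aligned = 60L,
  design_target_fraction = 0.88,
  scan_threshold = 0.80,
  qc_min_call_rate = 0.90,
  qc_min_dqc = 0.75,
  k_clusters = 4L,
  seed = 42L,
  log_level = "info"
)

#' Stage parameters for a workflow run
#'
#' @param ... overrides of the defaults: `filter_window`, `filter_identity`,
#'   `filter_min_aligned`, `design_target_fraction`, `scan_threshold`,
#'   `qc_min_call_rate`, `qc_min_dqc`, `k_clusters`, `seed`, `log_level`.
#'   Unknown keys are rejected.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    stop(sprintf("unknown run_config keys: %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, over)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file; unknown keys are rejected.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
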