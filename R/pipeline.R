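#' Run the full synthetic study end to end
#'
#' Simulates the subgenome pair, gene models, candidate pool and genotype
#' panel under one [sim_config()], then runs every analysis stage: the
#' filtering cascade, probe scoring/tiling and array selection, effect
#' annotation, panel QC, polymorphism partition and summary statistics,
#' density bookkeeping, allele-sharing distances with neighbor-joining
#' clustering, and the subspecies-specific high-frequency scan. Every random
#' draw derives from `config$seed`, so two runs with the same configuration
#' produce identical results (and identical files when `out_dir` is given).
#'
#' @param config a [sim_config()].
#' @param params a [run_config()] of stage parameters.
#' @param out_dir optional directory; when given, writes the manifest TSV,
#'   ledger and report JSON, genotype TSV, tree Newick and scan TSV.
#' @return list with every stage's outputs plus `report` (a JSON-ready
#'   summary) and `truth_eval` (recovery of the planted truth).
#' @export
run_pipeline <- function(config = sim_config(), params = run_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  log_msg <- function(fmt, ...) {
    if (identical(params$log_level, "quiet")) return(invisible())
    message(sprintf("[allosnp %6.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(fmt, ...)))
  }

  log_msg("simulating genomes (%d x 2 pseudomolecules, %d bp)",
          config$n_pseudomolecules_per_subgenome, config$pseudomolecule_length)
  g <- generate_genomes(config)
  cand <- generate_candidates(g$genomes, g$annotation, config)
  genomes <- cand$genomes
  log_msg("candidate pool: %d SNPs", nrow(cand$candidates))

  index <- build_genome_index(genomes)
  filt <- run_filter_pipeline(cand$candidates, genomes, g$annotation,
                              window = params$filter_window,
                              min_identity = params$filter_identity,
                              min_aligned = params$filter_min_aligned,
                              index = index)
  log_msg("filter cascade: %d passed of %d", filt$ledger$passed,
          filt$ledger$input)

  scored <- score_and_tile(filt$passed, known_variants = cand$candidates)
  effects <- classify_effect(scored, g$annotation, genomes)
  eligible <- exclude_transversion_ambiguous(scored)
  target <- max(1L, floor(params$design_target_fraction * nrow(eligible)))
  pm_lengths <- setNames(
    rep(config$pseudomolecule_length, 2 * config$n_pseudomolecules_per_subgenome),
    c(names(genomes$A), names(genomes$B)))
  manifest <- select_array(scored, target, pm_lengths, effect = effects)
  log_msg("array manifest: %d SNPs tiled", nrow(manifest))

  ann_summary <- summarize_annotation(
    effects[match(manifest$snp_id, effects$snp_id), ], manifest$subgenome)

  panel <- generate_panel(manifest, config)
  qc <- sample_qc(panel$panel, min_call_rate = params$qc_min_call_rate,
                  min_dqc = params$qc_min_dqc)
  summ <- snp_summary(qc$passed)
  part <- polymorphic_partition(qc$passed, "ploidy")
  dens <- density_stats(table(manifest$pseudomolecule),
                        pm_lengths / 1e6)
  log_msg("panel: %d samples passed QC, %d polymorphic SNPs",
          nrow(qc$passed$calls), length(part$combined))

  D <- allele_sharing_distance(qc$passed)
  tree <- neighbor_joining(D)
  clusters <- assign_clusters(tree, params$k_clusters)
  freqs <- category_frequencies(qc$passed)
  scan <- specific_high_frequency_scan(freqs, threshold = params$scan_threshold,
                                       snps = manifest)
  scan_eff <- scan_effect_filter(scan$snps, effects)
  log_msg("scan: %d specific high-frequency SNPs", scan$counts$total_specific)

  truth_eval <- evaluate_truth(cand$truth, filt, panel$truth, scan, clusters,
                               qc$passed)

  report <- list(
    config_seed = config$seed,
    ledger = unclass(filt$ledger),
    manifest = list(size = nrow(manifest),
                    per_subgenome = as.list(table(manifest$subgenome)),
                    per_recommendation = as.list(table(manifest$recommendation))),
    annotation = list(categories = setNames(as.list(ann_summary$both),
                                            ann_summary$category)),
    panel = list(samples_passed = nrow(qc$passed$calls),
                 samples_failed = nrow(qc$failed)),
    polymorphism = as.list(part$counts),
    summary_means = list(
      major_allele_freq = round(mean(summ$major_allele_freq, na.rm = TRUE), 4),
      minor_allele_freq = round(mean(summ$minor_allele_freq, na.rm = TRUE), 4),
      heterozygosity = round(mean(summ$observed_heterozygosity, na.rm = TRUE), 4),
      pic = round(mean(summ$pic, na.rm = TRUE), 4),
      gene_diversity = round(mean(summ$gene_diversity, na.rm = TRUE), 4)),
    density = dens$overall,
    scan = scan$counts[setdiff(names(scan$counts), "per_pseudomolecule")],
    truth_eval = truth_eval)

  out <- list(config = config, params = params, genomes = genomes,
              annotation = g$annotation, candidates = cand$candidates,
              truth = cand$truth, filter = filt, scored = scored,
              effects = effects, manifest = manifest,
              annotation_summary = ann_summary, panel = panel$panel,
              panel_truth = panel$truth, qc = qc, snp_summary = summ,
              partition = part, density = dens, distances = D, tree = tree,
              clusters = clusters, frequencies = freqs, scan = scan,
              scan_effects = scan_eff, report = report,
              truth_eval = truth_eval)

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# Recovery of the planted truth: filter confusion matrix, scan
# sensitivity/specificity, and cluster purity of the panel.
evaluate_truth <- function(truth, filt, panel_truth, scan, clusters, gm) {
  lab <- truth$labels
  oc <- filt$outcomes$outcome[match(lab$snp_id, filt$outcomes$snp_id)]
  expected <- c(true_variant = "passed",
                homeolog_artifact = "homeologous",
                duplicated_flank = "not_unique",
                multiallelic = "ambiguous_multiallelic")
  confusion <- table(truth = lab$label, outcome = oc)
  match_rate <- mean(oc == expected[lab$label])

  planted <- unlist(panel_truth$planted_specific, use.names = FALSE)
  called <- scan$snps$snp_id[scan$snps$class != "none"]
  present <- intersect(planted, scan$snps$snp_id)
  sens <- if (length(present)) mean(present %in% called) else NA_real_
  bg <- setdiff(scan$snps$snp_id, planted)
  spec <- if (length(bg)) mean(!(bg %in% called)) else NA_real_

  truth_cl <- panel_truth$clusters[names(clusters)]
  purity <- mean(vapply(split(truth_cl, clusters), function(x)
    max(table(x)) / length(x), numeric(1)))
  wild <- names(clusters)[truth_cl == "wild"]
  wild_isolated <- length(unique(clusters[wild])) == 1 &&
    !any(clusters[setdiff(names(clusters), wild)] %in% clusters[wild])

  list(filter_match_rate = match_rate,
       confusion = confusion,
       scan_sensitivity = sens,
       scan_specificity = spec,
       cluster_purity = purity,
       wild_isolated = wild_isolated)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- out$manifest
  num <- vapply(man, is.numeric, logical(1)) & names(man) != "position"
  man[num] <- lapply(man[num], function(x) round(x, 6))
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 6,
                       force = TRUE)
  write_genotypes(out$panel, file.path(out_dir, "genotypes.tsv"))
  write_tree_newick(out$tree, file.path(out_dir, "tree.nwk"))
  scan_tab <- merge(out$scan$snps, out$frequencies, by = "snp_id", sort = TRUE)
  scan_tab[-1] <- lapply(scan_tab[-1], function(x)
    if (is.numeric(x)) round(x, 6) else x)
  write.table(scan_tab, file.path(out_dir, "scan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- out$snp_summary
  summ[-1] <- lapply(summ[-1], function(x) if (is.numeric(x)) round(x, 6) else x)
  write.table(summ, file.path(out_dir, "snp_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
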