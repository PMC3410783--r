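# End-to-end orchestration: config -> stages -> machine-readable report.

#' Read and validate a pipeline run configuration
#'
#' The config is flat YAML with one nesting level. Exactly one of
#' `synthetic:` (generator parameters passed to [simulate_study()]) or
#' `inputs:` (paths: `mrna`, `ct`, `design`, `probe_map`, `predictions`,
#' `annotation`) must be present. `thresholds:` may override `mrna_fc`
#' (default 2), `mirna_fc` (4), `fdr` (0.05), `min_log2` (5),
#' `min_fraction` (0.5). A top-level `seed` drives every stochastic stage.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp) {
    abort("config must contain exactly one of 'synthetic' or 'inputs'")
  }
  defaults <- list(mrna_fc = 2, mirna_fc = 4, fdr = 0.05,
                   min_log2 = 5, min_fraction = 0.5)
  th <- utils::modifyList(defaults, config$thresholds %||% list())
  if (th$fdr <= 0 || th$fdr >= 1) abort("fdr must lie in (0, 1)")
  if (th$mrna_fc < 1 || th$mirna_fc < 1) abort("fold-change thresholds must be >= 1")
  config$thresholds <- th
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

stage_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}

#' Run the integrated miRNA-mRNA pipeline
#'
#' Executes the full analysis in order: input acquisition (synthetic
#' generation or file reading), mRNA quantile normalisation and
#' low-expression filtering, CT ceiling / detection / delta-CT / copy
#' number on the miRNA side, per-contrast differential expression with
#' fold-change + BH-FDR gates on both platforms, expression-pattern
#' classification, anti-correlation x prediction-database target pairing
#' with cross-database overlap, and gene-set enrichment including the
#' miRNA-regulated vs non-miRNA-regulated two-list comparison. Identical
#' config and seed give an identical report.
#'
#' @param config A config list (see [read_run_config()]) or a path to a
#'   YAML config file.
#' @param output_dir Directory for intermediate files and `report.json`;
#'   `NULL` keeps everything in memory.
#' @param quiet Suppress per-stage log lines.
#' @return A `run_report` object (list) with the counts, cutoffs, pattern
#'   and pairing summaries, top enriched terms and a config echo.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  th <- config$thresholds
  seed <- config$seed
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  emit <- function(writer, obj, file) {
    if (!is.null(output_dir)) writer(obj, file.path(output_dir, file))
  }

  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    study <- do.call(simulate_study, c(list(seed = seed), config$synthetic))
    design <- study$design; mrna_raw <- study$mrna; ct_raw <- study$ct
    probe_map <- study$probe_map; annotation <- study$annotation
    dbs <- list(study$db_a, study$db_b)
    truth <- study$truth
    emit(write_design_csv, design, "design.csv")
    emit(write_expression_tsv, mrna_raw, "mrna_raw.tsv")
    emit(write_ct_tsv, ct_raw, "mirna_ct_raw.tsv")
    emit(write_probe_map_tsv, probe_map, "probe_map.tsv")
    emit(write_ground_truth_json, truth, "ground_truth.json")
    stage_log(quiet, "simulate", nrow(mrna_raw), " probes, ",
              nrow(ct_raw) - 1L, " miRNAs, ", nrow(design), " samples")
  } else {
    inp <- config$inputs
    design <- read_design_csv(inp$design)
    mrna_raw <- read_expression_tsv(inp$mrna)
    ct_raw <- read_ct_tsv(inp$ct)
    probe_map <- read_probe_map_tsv(inp$probe_map)
    annotation <- read_gmt(inp$annotation,
                           universe = unique(read_probe_map_tsv(inp$probe_map)$gene_id))
    db_all <- read_predictions_tsv(inp$predictions)
    dbs <- split(db_all, db_all$source)
    truth <- NULL
    stage_log(quiet, "read", nrow(mrna_raw), " probes, ",
              nrow(ct_raw) - 1L, " miRNAs, ", nrow(design), " samples")
  }

  # -- mRNA normalisation ---------------------------------------------------
  mrna <- quantile_normalize(mrna_raw)
  mrna <- filter_low_expression(mrna, min_log2 = th$min_log2)
  emit(write_expression_tsv, mrna, "mrna_normalized_filtered.tsv")
  stage_log(quiet, "mrna_norm", nrow(mrna), " of ", nrow(mrna_raw),
            " probes kept after low-expression filter")

  # -- miRNA quantification -------------------------------------------------
  ct <- apply_ct_ceiling(ct_raw)
  detected <- detect_expressed(ct, design, min_fraction = th$min_fraction)
  dct <- normalize_delta_ct(ct, control_id = "U6")
  dct <- dct[dct$mirna_id %in% detected, , drop = FALSE]
  mirna_expr <- delta_ct_to_expression(dct)
  copy_tbl <- tibble(
    mirna_id = dct$mirna_id,
    copies = rowMeans(ct_to_copy_number(expr_to_matrix(
      ct[ct$mirna_id %in% detected, , drop = FALSE])))
  )
  emit(write_ct_tsv, dct, "delta_ct.tsv")
  stage_log(quiet, "mirna_quant", length(detected), " of ",
            nrow(ct_raw) - 1L, " miRNAs detected")

  # -- differential expression ---------------------------------------------
  run_de <- function(expr_tbl, fc_cutoff) {
    fit <- fit_cell_means(expr_tbl, design)
    res <- test_contrasts(fit)
    sig <- select_significant(res, fc_cutoff = fc_cutoff, fdr = th$fdr)
    cutoffs <- res %>%
      filter(!.data$degenerate) %>%
      group_by(.data$group) %>%
      summarise(p_cutoff = bh_p_cutoff(.data$p_raw, th$fdr), .groups = "drop")
    list(results = res, sig = sig, cutoffs = cutoffs)
  }
  de_mrna <- run_de(mrna, th$mrna_fc)
  de_mirna <- run_de(mirna_expr, th$mirna_fc)
  emit(function(x, f) readr::write_tsv(x, f), de_mrna$results, "contrasts_mrna.tsv")
  emit(function(x, f) readr::write_tsv(x, f), de_mirna$results, "contrasts_mirna.tsv")
  stage_log(quiet, "diffexp", nrow(de_mrna$sig), " significant mRNA calls, ",
            nrow(de_mirna$sig), " significant miRNA calls")

  patterns_mrna <- classify_patterns(de_mrna$sig, "mRNA")
  patterns_mirna <- classify_patterns(de_mirna$sig, "miRNA")
  emit(function(x, f) readr::write_tsv(x, f), patterns_mrna, "patterns_mrna.tsv")
  emit(function(x, f) readr::write_tsv(x, f), patterns_mirna, "patterns_mirna.tsv")

  # -- target integration ---------------------------------------------------
  candidates <- candidate_pairs(de_mirna$sig, de_mrna$sig)
  pair_sets <- lapply(dbs, function(db) {
    intersect_predictions(candidates, db, probe_map)
  })
  names(pair_sets) <- vapply(pair_sets, function(ps) ps$source, character(1))
  overlap <- if (length(pair_sets) >= 2) {
    cross_database_overlap(pair_sets[[1]], pair_sets[[2]])
  } else character()
  for (ps in pair_sets) {
    emit(function(x, f) readr::write_tsv(x, f), tidy(ps),
         paste0("pairs_", ps$source, ".tsv"))
  }
  stage_log(quiet, "integrate", length(candidates$mirna_id), " candidates; ",
            paste(vapply(pair_sets, function(ps)
              paste0(ps$source, ": ", ps$n_pairs, " pairs"), character(1)),
              collapse = ", "))

  # -- enrichment -----------------------------------------------------------
  responsive_probes <- unique(
    de_mrna$sig$probe_id[de_mrna$sig$group %in% c("B", "C")])
  responsive_genes <- probe_map$gene_id[probe_map$probe_id %in% responsive_probes]
  responsive_genes <- intersect(unique(responsive_genes), annotation$universe)
  regulated <- intersect(
    unique(unlist(lapply(pair_sets, function(ps) ps$unique_mrnas))),
    responsive_genes)
  unregulated <- setdiff(responsive_genes, regulated)
  enrichment <- if (length(responsive_genes) > 0) {
    enrich_terms(responsive_genes, annotation)
  } else NULL
  top <- if (!is.null(enrichment)) top_terms(enrichment) else NULL
  comparison <- if (length(regulated) > 0 && length(unregulated) > 0) {
    compare_term_enrichment(regulated, unregulated, annotation)
  } else NULL
  if (!is.null(enrichment)) {
    emit(function(x, f) readr::write_tsv(x, f), enrichment, "enrichment.tsv")
  }
  if (!is.null(comparison)) {
    emit(function(x, f) readr::write_tsv(x, f), comparison,
         "enrichment_comparison.tsv")
  }
  stage_log(quiet, "enrich", length(responsive_genes),
            " responsive genes (", length(regulated), " miRNA-regulated)")

  # -- report ---------------------------------------------------------------
  count_sig <- function(sig) {
    sig %>%
      count(.data$group, .data$sign) %>%
      tidyr::pivot_wider(names_from = "sign", values_from = "n",
                         values_fill = 0L)
  }
  report <- structure(
    list(
      seed = seed,
      thresholds = th,
      n_samples = nrow(design),
      n_probes_input = nrow(mrna_raw),
      n_probes_kept = nrow(mrna),
      n_mirnas_input = nrow(ct_raw) - 1L,
      n_mirnas_detected = length(detected),
      significant_mrna = count_sig(de_mrna$sig),
      significant_mirna = count_sig(de_mirna$sig),
      p_cutoffs_mrna = de_mrna$cutoffs,
      p_cutoffs_mirna = de_mirna$cutoffs,
      pattern_counts_mrna = count(patterns_mrna, .data$pattern),
      pattern_counts_mirna = count(patterns_mirna, .data$pattern),
      n_candidates = nrow(candidates),
      pair_summary = lapply(pair_sets, glance) %>% list_rbind(),
      n_overlap_mrnas = length(overlap),
      top_terms = top,
      enrichment_comparison = comparison,
      truth = truth
    ),
    class = "run_report"
  )
  if (!is.null(output_dir)) {
    serializable <- report[setdiff(names(report), "truth")]
    jsonlite::write_json(serializable, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  cat("  probes:", x$n_probes_kept, "kept of", x$n_probes_input,
      "| miRNAs detected:", x$n_mirnas_detected, "of", x$n_mirnas_input, "\n")
  cat("  significant calls: mRNA", sum(x$significant_mrna[-1]),
      "| miRNA", sum(x$significant_mirna[-1]), "\n")
  if (nrow(x$pair_summary) > 0) {
    for (i in seq_len(nrow(x$pair_summary))) {
      cat("  ", x$pair_summary$source[i], ": ", x$pair_summary$n_pairs[i],
          " pairs, ", x$pair_summary$n_unique_mrnas[i], " unique mRNAs\n",
          sep = "")
    }
  }
  cat("  cross-database overlap:", x$n_overlap_mrnas, "mRNAs\n")
  invisible(x)
}
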