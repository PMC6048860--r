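#' Pipeline configuration
#'
#' All tunable thresholds of the integrative analysis with their standard
#' defaults: gain/loss calling at +/-0.15 log2-ratio, segment FDR <= 1e-05,
#' minimum segment length 1 kb and 10 probes, recurrence in >= 10% of
#' patients, one-sided concordance at p < 0.05, 100-gene AGS tails, common
#' AGS recurrence in >= 5 patients, driver calling at z > 2, 50 bootstrap
#' replicates. The configuration is echoed into the run report for
#' provenance.
#'
#' @param gain_threshold,loss_threshold,max_fdr,min_length_bp,min_probes,recurrence_fraction,penalty_mult,penalty see [segmentation_params()].
#' @param concordance_alpha one-sided Welch significance for the FGS filter.
#' @param ags_top_n genes per AGS tail.
#' @param common_ags_min_recurrence patient count for the common AGS.
#' @param nea_null_kind NEA null model (see [nea_zscore()]).
#' @param z_threshold driver-calling z threshold.
#' @param bootstrap_B bootstrap replicates.
#' @param bootstrap_p_null per-replicate null selection probability (`NULL`:
#'   derived as observed drivers / annotated genes).
#' @param literature_genes character vector of literature AGS genes.
#' @param dgscore_mode DGscore mode (see [compute_dgscore()]).
#' @param seed master seed for all stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(gain_threshold = 0.15, loss_threshold = -0.15,
                            max_fdr = 1e-05, min_length_bp = 1000,
                            min_probes = 10, recurrence_fraction = 0.10,
                            penalty_mult = 2, penalty = NULL,
                            concordance_alpha = 0.05, ags_top_n = 100,
                            common_ags_min_recurrence = 5,
                            nea_null_kind = "hypergeometric",
                            z_threshold = 2, bootstrap_B = 50,
                            bootstrap_p_null = NULL,
                            literature_genes = character(),
                            dgscore_mode = "all", seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

seg_params_of <- function(config) {
  segmentation_params(gain_threshold = config$gain_threshold,
                      loss_threshold = config$loss_threshold,
                      max_fdr = config$max_fdr,
                      min_length_bp = config$min_length_bp,
                      min_probes = config$min_probes,
                      recurrence_fraction = config$recurrence_fraction,
                      penalty_mult = config$penalty_mult,
                      penalty = config$penalty)
}

#' Run the full integrative driver-gene pipeline
#'
#' Executes segmentation, CNA filtering, recurrent-region detection, FGS and
#' AGS construction, network enrichment driver calling (common and
#' patient-specific), DGscore computation, median-split survival validation
#' (Kaplan-Meier / log-rank and the Cox model set), and optionally the
#' bootstrap stability analysis.
#'
#' @param cohort a [generate_cohort()] object, or a list with the same
#'   elements read from files (`probe_map`, `log_ratios`, `expression`,
#'   `gene_annotation`, `network`, `clinical`).
#' @param config a [pipeline_config()].
#' @param bootstrap if `TRUE`, run [bootstrap_common_drivers()] at the end.
#' @param output_dir optional directory; when given, stage outputs (segments,
#'   regions BED, gene sets, drivers, scores, report JSON) are written there.
#' @return Object of class `dgscore_run`: all stage objects plus a `report`
#'   list with per-stage counts, driver lists, survival statistics and the
#'   config echo.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         bootstrap = FALSE, output_dir = NULL) {
  params <- seg_params_of(config)
  patients <- cohort$clinical$patient
  stopifnot(identical(sort(colnames(cohort$log_ratios)), sort(patients)),
            identical(sort(colnames(cohort$expression)), sort(patients)))

  log_stage <- function(...) message("[dgscore] ", ...)

  log_stage("segmenting ", length(patients), " profiles")
  segments <- segment_cohort(cohort$probe_map, cohort$log_ratios, params,
                             filter = FALSE)
  cnas <- filter_segments(segments, params)
  attr(cnas, "probe_map") <- cohort$probe_map

  log_stage("detecting recurrent regions")
  regions <- detect_recurrent_regions(cnas, length(patients),
                                      cohort$probe_map,
                                      params$recurrence_fraction)

  log_stage("building gene sets")
  expr <- preprocess_expression(cohort$expression)
  fgs <- build_fgs(regions, cohort$gene_annotation, expr, cnas,
                   alpha = config$concordance_alpha)
  fgs_common <- build_common_fgs(fgs)
  ags_list <- lapply(patients, function(p)
    build_patient_ags(expr, p, config$ags_top_n))
  names(ags_list) <- patients
  universe <- union(igraph::V(cohort$network)$name, rownames(cohort$expression))
  ags_common <- suppressWarnings(build_common_ags(
    ags_list, config$common_ags_min_recurrence, config$literature_genes,
    universe))

  log_stage("network enrichment analysis")
  common_drivers <- call_common_drivers(fgs_common, ags_common,
                                        cohort$network,
                                        z_threshold = config$z_threshold,
                                        null_kind = config$nea_null_kind,
                                        seed = config$seed)
  patient_drivers <- call_patient_drivers(fgs, ags_list, cohort$network,
                                          z_threshold = config$z_threshold,
                                          null_kind = config$nea_null_kind,
                                          seed = config$seed)

  log_stage("DGscore and survival validation")
  scores <- compute_dgscore(common_drivers, patient_drivers, fgs, patients,
                            mode = config$dgscore_mode)
  survival_res <- NULL
  cox <- NULL
  split_scores <- try(median_split(scores), silent = TRUE)
  if (!inherits(split_scores, "try-error")) {
    survival_res <- km_logrank(split_scores[, c("patient", "group")],
                               cohort$clinical)
    cox <- cox_models(split_scores, cohort$clinical)
    scores <- split_scores
  } else {
    warning("degenerate DGscore split; survival validation skipped")
  }

  boot <- NULL
  if (bootstrap) {
    log_stage("bootstrap stability (B = ", config$bootstrap_B, ")")
    boot <- bootstrap_common_drivers(
      cnas, cohort$expression, cohort$gene_annotation, cohort$network,
      B = config$bootstrap_B, seed = config$seed,
      p_null = config$bootstrap_p_null,
      observed_drivers = common_drivers$gene,
      params = params, ags_top_n = config$ags_top_n,
      ags_min_recurrence = config$common_ags_min_recurrence,
      literature_genes = config$literature_genes,
      concordance_alpha = config$concordance_alpha,
      z_threshold = config$z_threshold, null_kind = config$nea_null_kind)
  }

  report <- list(
    n_patients = length(patients),
    n_segments = nrow(segments),
    n_cnas = nrow(cnas),
    n_recurrent_regions = nrow(regions$regions),
    recurrence_threshold = regions$threshold,
    n_annotated_genes = length(unique(fgs$annotation$gene)),
    n_fgs_genes = length(fgs$genes),
    n_fgs_common_genes = nrow(fgs_common),
    n_ags_common_genes = nrow(ags_common),
    common_drivers = common_drivers$gene,
    n_patient_specific_drivers = length(unique(patient_drivers$gene)),
    median_drivers_per_patient = stats::median(scores$dgscore),
    logrank_p = if (!is.null(survival_res)) survival_res$p else NA_real_,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    seed = config$seed)

  run <- structure(list(
    segments = segments, cnas = cnas, regions = regions, expr = expr,
    fgs = fgs, fgs_common = fgs_common, patient_ags = ags_list,
    ags_common = ags_common, common_drivers = common_drivers,
    patient_drivers = patient_drivers, scores = scores,
    survival = survival_res, cox = cox, bootstrap = boot,
    clinical = cohort$clinical, report = report), class = "dgscore_run")

  if (!is.null(output_dir)) write_run(run, output_dir, config)
  run
}

write_run <- function(run, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stage_tsv(run$cnas, file.path(dir, "segments.tsv"), "segment", config)
  write_regions_bed(run$regions$regions, file.path(dir, "regions.bed"), config)
  gs <- rbind(
    data.frame(gene = run$fgs$genes, provenance = "fgs_full",
               direction = NA_character_, stringsAsFactors = FALSE),
    if (nrow(run$fgs_common)) data.frame(gene = run$fgs_common$gene,
                                         provenance = "fgs_common",
                                         direction = run$fgs_common$direction,
                                         stringsAsFactors = FALSE),
    if (nrow(run$ags_common)) data.frame(gene = run$ags_common$gene,
                                         provenance = "ags_common",
                                         direction = NA_character_,
                                         stringsAsFactors = FALSE))
  write_stage_tsv(gs, file.path(dir, "gene_sets.tsv"), "fgs_ags", config)
  drv <- rbind(run$common_drivers, run$patient_drivers)
  write_stage_tsv(drv, file.path(dir, "drivers.tsv"), "nea", config)
  write_stage_tsv(run$scores, file.path(dir, "scores.tsv"), "score", config)
  if (!is.null(run$bootstrap)) {
    write_stage_tsv(run$bootstrap$counts, file.path(dir, "bootstrap.tsv"),
                    "bootstrap", config)
  }
  rep <- run$report
  if (!is.null(run$cox)) rep$cox <- run$cox
  jsonlite::write_json(rep, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.dgscore_run <- function(x, ...) {
  r <- x$report
  cat("dgscore run:", r$n_patients, "patients\n")
  cat("  CNAs:", r$n_cnas, " recurrent regions:", r$n_recurrent_regions,
      " annotated genes:", r$n_annotated_genes, "\n")
  cat("  FGS:", r$n_fgs_genes, " (direction-pure:", r$n_fgs_common_genes,
      ")  common AGS:", r$n_ags_common_genes, "\n")
  cat("  common drivers:", if (length(r$common_drivers))
    paste(r$common_drivers, collapse = ", ") else "none", "\n")
  cat("  patient-specific drivers:", r$n_patient_specific_drivers,
      " median DGscore:", r$median_drivers_per_patient, "\n")
  if (!is.na(r$logrank_p)) cat("  log-rank p (DGscore split):",
                               format.pval(r$logrank_p, digits = 3), "\n")
  invisible(x)
}
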