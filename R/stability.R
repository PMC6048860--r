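#' Exact upper-tail binomial p-value
#'
#' `P(X >= x)` for `X ~ Binomial(n, p)`, accumulated in log space so that
#' extremely small tails (down to the double-precision floor) keep full
#' relative accuracy. Used as the null distribution of how often a gene is
#' selected as a common driver across bootstrap replicates when, under the
#' no-driver null, each replicate selects a gene with probability `p`.
#'
#' @param x observed selection count (0 <= x <= n).
#' @param n number of replicates.
#' @param p per-replicate selection probability, in (0, 1).
#' @return The exact tail probability, in (0, 1].
#' @export
binomial_tail_pvalue <- function(x, n, p) {
  stopifnot(length(x) == 1, length(n) == 1, length(p) == 1)
  if (x < 0 || x != round(x) || n < 1 || n != round(n)) {
    stop("input error: x and n must be nonnegative integers", call. = FALSE)
  }
  if (x > n) stop("input error: x > n", call. = FALSE)
  if (p <= 0 || p >= 1) stop("input error: p must be in (0, 1)", call. = FALSE)
  if (x == 0) return(1)
  lp <- stats::dbinom(x:n, n, p, log = TRUE)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

## One full common-driver analysis from per-patient CNAs + expression.
## Shared by run_pipeline() and the bootstrap; `patients` may contain
## duplicated source patients under unique aliases (bootstrap resampling).
common_driver_analysis <- function(cnas, expression_values, gene_annotation,
                                   network, n_patients,
                                   params = segmentation_params(),
                                   ags_top_n = 100, ags_min_recurrence = 5,
                                   literature_genes = character(),
                                   concordance_alpha = 0.05,
                                   z_threshold = 2,
                                   null_kind = "hypergeometric", seed = 1L) {
  regions <- detect_recurrent_regions(cnas, n_patients, attr(cnas, "probe_map"),
                                      recurrence_fraction = params$recurrence_fraction)
  expr <- preprocess_expression(expression_values)
  fgs <- build_fgs(regions, gene_annotation, expr, cnas,
                   alpha = concordance_alpha)
  fgs_common <- build_common_fgs(fgs)
  pats <- colnames(expression_values)
  ags_list <- lapply(pats, function(p) build_patient_ags(expr, p, ags_top_n))
  names(ags_list) <- pats
  universe <- union(igraph::V(network)$name, rownames(expression_values))
  ags_common <- suppressWarnings(
    build_common_ags(ags_list, ags_min_recurrence, literature_genes, universe))
  common <- call_common_drivers(fgs_common, ags_common, network,
                                z_threshold = z_threshold,
                                null_kind = null_kind, seed = seed)
  list(regions = regions, expr = expr, fgs = fgs, fgs_common = fgs_common,
       patient_ags = ags_list, ags_common = ags_common, common_drivers = common)
}

#' Bootstrap stability of common-driver detection
#'
#' Resamples patients with replacement `B` times; for each replicate the full
#' common-driver pipeline (recurrent regions on the resampled CNA profiles,
#' concordance-filtered FGS, direction-pure reduction, common AGS, network
#' enrichment at `z > z_threshold`) is rerun on the resampled cohort, keeping
#' each resampled patient's omics columns linked. The number of times each
#' gene is selected is compared against an exact binomial null with
#' per-replicate selection probability `p_null` (by default, observed common
#' drivers divided by annotated recurrent genes in the full cohort).
#'
#' @param cnas pooled filtered CNAs of the cohort, with the probe map attached
#'   as attribute `"probe_map"` (as produced by [run_pipeline()]'s
#'   segmentation stage, or set manually).
#' @param expression_values gene x patient FPKM matrix.
#' @param gene_annotation gene coordinate table.
#' @param network undirected igraph network.
#' @param B bootstrap replicates (default 50).
#' @param seed master seed; replicate seeds are fixed increments of it.
#' @param p_null per-replicate null selection probability; `NULL` derives it
#'   from the full-cohort analysis.
#' @param observed_drivers optionally, the full-cohort common driver genes
#'   (used to derive `p_null` and to order the output); computed if `NULL`.
#' @param ... further arguments passed to the per-replicate analysis
#'   (`ags_top_n`, `ags_min_recurrence`, `literature_genes`,
#'   `concordance_alpha`, `z_threshold`, `null_kind`, `params`).
#' @return List with `counts` (data frame: `gene`, `x`, `B`, `proportion`,
#'   `p_null`, `p_value`, sorted by decreasing `x`), `p_null_derived`
#'   (observed drivers / annotated genes) and `B`.
#' @export
bootstrap_common_drivers <- function(cnas, expression_values, gene_annotation,
                                     network, B = 50, seed = 1L,
                                     p_null = NULL, observed_drivers = NULL,
                                     ...) {
  if (B < 1) stop("invalid-config: B must be >= 1", call. = FALSE)
  patients <- colnames(expression_values)
  n <- length(patients)

  full <- common_driver_analysis(cnas, expression_values, gene_annotation,
                                 network, n, seed = seed, ...)
  n_annotated <- length(unique(full$fgs$annotation$gene))
  obs <- if (is.null(observed_drivers)) full$common_drivers$gene else observed_drivers
  p_derived <- if (n_annotated > 0) length(obs) / n_annotated else NA_real_
  if (is.null(p_null)) p_null <- p_derived
  probe_map <- attr(cnas, "probe_map")

  tally <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample(n, n, replace = TRUE)
    alias <- sprintf("%s.b%02d", patients[idx], seq_len(n))
    ## resampled CNAs: duplicate each drawn patient's segments under its alias
    cn_b <- do.call(rbind, lapply(seq_len(n), function(j) {
      rows <- cnas[cnas$patient == patients[idx[j]], , drop = FALSE]
      if (nrow(rows)) rows$patient <- alias[j]
      rows
    }))
    attr(cn_b, "probe_map") <- probe_map
    ex_b <- expression_values[, idx, drop = FALSE]
    colnames(ex_b) <- alias
    rep_res <- try(common_driver_analysis(cn_b, ex_b, gene_annotation, network,
                                          n, seed = seed + b, ...),
                   silent = TRUE)
    if (inherits(rep_res, "try-error")) next
    for (g in unique(rep_res$common_drivers$gene)) {
      tally[[g]] <- (if (is.null(tally[[g]])) 0L else tally[[g]]) + 1L
    }
  }
  genes <- union(obs, ls(tally))
  x <- vapply(genes, function(g) if (is.null(tally[[g]])) 0L else tally[[g]],
              integer(1))
  pv <- if (is.finite(p_null) && p_null > 0 && p_null < 1) {
    vapply(x, binomial_tail_pvalue, numeric(1), n = B, p = p_null)
  } else {
    rep(NA_real_, length(x))
  }
  counts <- data.frame(gene = genes, x = x, B = B, proportion = x / B,
                       p_null = p_null, p_value = pv,
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$x, counts$gene), ]
  rownames(counts) <- NULL
  list(counts = counts, p_null_derived = p_derived, B = B,
       observed_drivers = obs)
}
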