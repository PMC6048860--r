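#' Per-patient driver-gene score (DGscore)
#'
#' The DGscore of a patient is the number of called driver genes that the
#' patient actually carries as copy-number alterations: common drivers count
#' for a patient only when covered by that patient's own filtered CNAs, and
#' patient-specific drivers count only for their patient. Alternative modes
#' reproduce the comparison splits of lower levels of integration.
#'
#' @param common_calls data frame from [call_common_drivers()].
#' @param patient_calls data frame from [call_patient_drivers()].
#' @param fgs output of [build_fgs()] (per-patient alteration states and the
#'   FGS gene pool).
#' @param patients character vector of all patient ids (patients with no
#'   drivers get score 0).
#' @param mode `"all"` (default; union of carried common drivers and own
#'   patient-specific drivers), `"common_only"`, `"patient_specific_only"`, or
#'   `"raw_fgs"` (counts every FGS gene altered in the patient, with no
#'   network-enrichment filter).
#' @return Data frame of class `patient_scores`: `patient`, `dgscore`,
#'   `drivers` (comma-separated contributing genes).
#' @export
compute_dgscore <- function(common_calls, patient_calls, fgs, patients,
                            mode = c("all", "common_only",
                                     "patient_specific_only", "raw_fgs")) {
  mode <- match.arg(mode)
  alt <- fgs$alterations
  bad <- setdiff(unique(patient_calls$scope), patients)
  if (length(bad)) {
    stop("input error: driver calls for unknown patient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- lapply(patients, function(p) {
    altered <- alt$gene[alt$patient == p]
    common_carried <- intersect(common_calls$gene, altered)
    own <- patient_calls$gene[patient_calls$scope == p]
    drivers <- switch(mode,
      all = union(common_carried, own),
      common_only = common_carried,
      patient_specific_only = unique(own),
      raw_fgs = intersect(fgs$genes, altered))
    data.frame(patient = p, dgscore = length(drivers),
               drivers = paste(sort(drivers), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("patient_scores", "data.frame")
  out
}

#' Split patients into high / low score groups at the cohort median
#'
#' High means strictly greater than the median score; ties at the median go to
#' the low group. Both groups must be nonempty.
#'
#' @param scores data frame with `patient` and `dgscore` (or any numeric
#'   `value` column named by `column`).
#' @param column name of the numeric column to split on.
#' @return The input with an added `group` factor (`low`/`high`).
#' @export
median_split <- function(scores, column = "dgscore") {
  v <- scores[[column]]
  if (length(v) < 2) stop("need at least 2 patients", call. = FALSE)
  med <- stats::median(v)
  group <- ifelse(v > med, "high", "low")
  if (length(unique(group)) < 2) {
    stop("degenerate-split: median split leaves an empty group", call. = FALSE)
  }
  scores$group <- factor(group, levels = c("low", "high"))
  scores
}

#' Kaplan-Meier curves and log-rank test for a two-group split
#'
#' @param groups data frame with `patient` and `group` (from
#'   [median_split()]).
#' @param clinical clinical table with `patient`, `os_days`, `os_event`.
#' @return List with `fit` (a [survival::survfit] object), `chisq` (log-rank
#'   statistic), `df` and `p` (log-rank p-value). A group without events
#'   triggers a warning but the test is still computed.
#' @export
km_logrank <- function(groups, clinical) {
  d <- merge(groups, clinical, by = "patient")
  if (nrow(d) < nrow(groups)) {
    stop("input error: missing survival data for some grouped patients",
         call. = FALSE)
  }
  ev <- tapply(d$os_event, d$group, sum)
  if (any(ev == 0)) {
    warning("group(s) with zero events: ",
            paste(names(ev)[ev == 0], collapse = ", "))
  }
  fit <- survival::survfit(survival::Surv(os_days, os_event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(os_days, os_event) ~ group,
                            data = d)
  df <- length(sd_$n) - 1
  p <- stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd_$chisq), df = df, p = p)
}

## Model formulas of the standard validation set: DGscore alone, each
## clinical factor alone, DGscore adjusted for each, and the full model.
cox_model_specs <- function() {
  list(
    "1a" = ~ dgscore_group,
    "1b" = ~ stage4,
    "1c" = ~ mycn_amp,
    "1d" = ~ age_days,
    "2"  = ~ dgscore_group + stage4,
    "3"  = ~ dgscore_group + mycn_amp,
    "4"  = ~ dgscore_group + age_days,
    "5"  = ~ age_days + mycn_amp + stage4,
    "6"  = ~ dgscore_group + age_days + mycn_amp + stage4)
}

#' Cox proportional-hazards validation models
#'
#' Fits the standard set of survival models: DGscore alone (model 1a), each
#' known clinical prognostic factor alone (1b tumour stage, 1c MYCN
#' amplification, 1d age), DGscore adjusted for each factor (models 2-4), the
#' three clinical factors together (model 5) and the full model (6). DGscore
#' enters as the binary high/low median-split group by default (set
#' `dgscore_as` to `"continuous"` for the raw count); stage is binary 4/4S
#' versus 1-3; MYCN reference is non-amplified; age is continuous in days.
#'
#' @param scores output of [median_split()] (needs `group`; `dgscore` for the
#'   continuous coding).
#' @param clinical clinical table (`patient`, `os_days`, `os_event`,
#'   `age_days`, `stage`, `mycn_amp`).
#' @param dgscore_as `"binary"` (default) or `"continuous"`.
#' @return Data frame with `model_id`, `variable`, `hazard_ratio`, `p`
#'   (Wald), `note` (`"ok"`, `"non-identifiable"` for a constant covariate, or
#'   the error message for a failed fit).
#' @export
cox_models <- function(scores, clinical, dgscore_as = c("binary", "continuous")) {
  dgscore_as <- match.arg(dgscore_as)
  d <- merge(scores, clinical, by = "patient")
  d$dgscore_group <- if (dgscore_as == "binary") {
    as.integer(d$group == "high")
  } else {
    d$dgscore
  }
  d$stage4 <- as.integer(d$stage %in% c("4", "4S"))
  pretty <- c(dgscore_group = "DGscore", stage4 = "Tumor stage",
              mycn_amp = "MYCN amplification", age_days = "Age")
  res <- list()
  for (mid in names(cox_model_specs())) {
    fml <- stats::as.formula(paste(
      "survival::Surv(os_days, os_event)",
      paste(deparse(cox_model_specs()[[mid]]), collapse = "")))
    vars <- all.vars(cox_model_specs()[[mid]])
    const <- vars[vapply(vars, function(v) length(unique(d[[v]])) < 2, logical(1))]
    if (length(const)) {
      res[[mid]] <- data.frame(model_id = mid, variable = pretty[const],
                               hazard_ratio = NA_real_, p = NA_real_,
                               note = "non-identifiable", stringsAsFactors = FALSE)
      next
    }
    fit <- try(survival::coxph(fml, data = d), silent = TRUE)
    if (inherits(fit, "try-error")) {
      res[[mid]] <- data.frame(model_id = mid, variable = paste(vars, collapse = "+"),
                               hazard_ratio = NA_real_, p = NA_real_,
                               note = as.character(fit), stringsAsFactors = FALSE)
      next
    }
    sm <- summary(fit)$coefficients
    res[[mid]] <- data.frame(model_id = mid,
                             variable = unname(pretty[rownames(sm)]),
                             hazard_ratio = unname(sm[, "exp(coef)"]),
                             p = unname(sm[, "Pr(>|z|)"]),
                             note = "ok", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Survival split by a single gene's expression
#'
#' Median-splits the cohort on one gene's expression (e.g. a comparator
#' biomarker such as TERT) and runs the Kaplan-Meier / log-rank comparison.
#'
#' @param expr an [preprocess_expression()] object.
#' @param gene gene id present in the expression matrix.
#' @param clinical clinical table.
#' @return As [km_logrank()], plus the `groups` data frame used.
#' @export
single_gene_split <- function(expr, gene, clinical) {
  if (!gene %in% rownames(expr$values)) {
    stop("input error: gene not in expression matrix: ", gene, call. = FALSE)
  }
  sc <- data.frame(patient = colnames(expr$values),
                   value = expr$values[gene, ], stringsAsFactors = FALSE)
  sc <- median_split(sc, column = "value")
  out <- km_logrank(sc[, c("patient", "group")], clinical)
  out$groups <- sc
  out
}
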