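#' Segmentation and CNA-calling parameters
#'
#' Thresholds for copy-number calling. Defaults: a segment is called a gain at
#' mean log2-ratio >= +0.15 and a loss at <= -0.15; called segments are kept
#' only with FDR-adjusted significance <= 1e-05, length >= 1 kb and >= 10
#' probes; a region is recurrent when altered in at least 10% of patients
#' (ceiling rule, so 48 patients give a threshold of 5 carriers).
#'
#' @param gain_threshold log2-ratio at or above which a segment mean is a gain.
#' @param loss_threshold log2-ratio at or below which a segment mean is a loss.
#' @param max_fdr maximum BH-adjusted segment q-value kept by
#'   [filter_segments()].
#' @param min_length_bp minimum segment length kept, in bp.
#' @param min_probes minimum number of probes in a kept segment.
#' @param recurrence_fraction minimum fraction of patients altered for a probe
#'   to lie in a recurrent region.
#' @param penalty_mult multiplier c in the changepoint penalty
#'   `c * sigma_hat^2 * log(n)`; 2 gives a BIC-like criterion.
#' @param penalty optional absolute changepoint penalty overriding the
#'   BIC-like default.
#'
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(gain_threshold = 0.15,
                                loss_threshold = -0.15,
                                max_fdr = 1e-05,
                                min_length_bp = 1000,
                                min_probes = 10,
                                recurrence_fraction = 0.10,
                                penalty_mult = 2,
                                penalty = NULL) {
  stopifnot(gain_threshold > 0, loss_threshold < 0,
            recurrence_fraction > 0, recurrence_fraction < 1,
            max_fdr > 0, min_probes >= 1, min_length_bp >= 0,
            is.null(penalty) || penalty > 0, penalty_mult > 0)
  structure(as.list(environment()), class = "segmentation_params")
}

## Optimal partitioning of x into constant-mean pieces minimising
## SSE + penalty * (#segments), by dynamic programming (vectorised O(n^2)).
## Returns the sorted last indices of each segment (n always included).
find_changepoints <- function(x, penalty) {
  n <- length(x)
  if (n < 2) return(n)
  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  best <- numeric(n + 1)   # best[t+1] = optimal cost of x[1..t]
  prev <- integer(n + 1)
  best[1] <- -penalty
  for (t in seq_len(n)) {
    s <- 0:(t - 1)
    len <- t - s
    sse <- (css[t + 1] - css[s + 1]) - (cs[t + 1] - cs[s + 1])^2 / len
    cand <- best[s + 1] + sse + penalty
    j <- which.min(cand)
    best[t + 1] <- cand[j]
    prev[t + 1] <- s[j]
  }
  ends <- integer(0)
  t <- n
  while (t > 0) {
    ends <- c(t, ends)
    t <- prev[t + 1]
  }
  ends
}

## Robust noise scale from successive differences (immune to mean shifts):
## sd_hat = 1.4826 * median(|diff(x)|) / sqrt(2), pooled within chromosomes.
robust_noise_sd <- function(values, chrom) {
  d <- unlist(lapply(split(values, chrom), function(v) {
    if (length(v) >= 2) abs(diff(v)) else numeric(0)
  }), use.names = FALSE)
  if (!length(d)) return(NA_real_)
  s <- 1.4826 * stats::median(d) / sqrt(2)
  if (s <= 0) s <- max(1e-8, stats::sd(values))
  s
}

#' Segment one patient's probe log-ratios into copy-number segments
#'
#' Per chromosome, fits a piecewise-constant mean by penalised least-squares
#' changepoint detection (penalty `penalty_mult * sigma_hat^2 * log(n)` with a
#' robust noise scale estimated from successive probe differences). Each
#' segment is tested against mean 0 (two-sided normal on
#' `mean * sqrt(n_probes) / sigma_hat`), p-values are BH-adjusted across all
#' of the patient's segments into `q_value`, and states are assigned by the
#' gain/loss thresholds. Segments partition each chromosome's probes.
#'
#' @param probe_map data frame with columns `probe`, `chrom`, `pos`, sorted by
#'   (chrom, pos).
#' @param log_ratios numeric vector of per-probe log2 ratios, aligned with
#'   `probe_map` rows.
#' @param params a [segmentation_params()] object.
#' @param patient patient id recorded in the output.
#'
#' @return Data frame of class `cna_segments` with columns `patient`, `chrom`,
#'   `start`, `end` (0-based half-open, end = last probe position + 1),
#'   `first_probe`, `last_probe` (row indices into `probe_map`), `n_probes`,
#'   `mean_lr`, `p_value`, `q_value`, `state`.
#' @export
segment_profile <- function(probe_map, log_ratios, params = segmentation_params(),
                            patient = "sample") {
  if (!all(is.finite(log_ratios))) {
    stop("input error: non-finite log-ratios", call. = FALSE)
  }
  stopifnot(nrow(probe_map) == length(log_ratios))
  chroms <- unique(probe_map$chrom)
  s_hat <- robust_noise_sd(log_ratios, probe_map$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    rows <- which(probe_map$chrom == chroms[ci])
    if (is.unsorted(probe_map$pos[rows])) {
      stop("input error: probes not sorted by position on ", chroms[ci],
           call. = FALSE)
    }
    x <- log_ratios[rows]
    n <- length(x)
    if (n < 2) {
      ends <- n
    } else {
      pen <- if (!is.null(params$penalty)) params$penalty
             else params$penalty_mult * s_hat^2 * log(n)
      ends <- find_changepoints(x, pen)
    }
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    mean_lr <- vapply(seq_along(ends),
                      function(i) mean(x[starts[i]:ends[i]]), numeric(1))
    n_probes <- ends - starts + 1L
    out[[ci]] <- data.frame(
      patient = patient, chrom = chroms[ci],
      start = probe_map$pos[rows[starts]],
      end = probe_map$pos[rows[ends]] + 1L,
      first_probe = rows[starts], last_probe = rows[ends],
      n_probes = n_probes, mean_lr = mean_lr,
      stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, out)
  z <- seg$mean_lr * sqrt(seg$n_probes) / s_hat
  seg$p_value <- 2 * stats::pnorm(-abs(z))
  seg$q_value <- stats::p.adjust(seg$p_value, method = "BH")
  seg$state <- ifelse(seg$mean_lr >= params$gain_threshold, "gain",
                      ifelse(seg$mean_lr <= params$loss_threshold, "loss",
                             "neutral"))
  class(seg) <- c("cna_segments", "data.frame")
  seg
}

#' Filter called segments down to confident CNAs
#'
#' Keeps only non-neutral segments with `q_value <= max_fdr`, length
#' `>= min_length_bp` and `>= min_probes` probes.
#'
#' @param segments output of [segment_profile()] (may pool several patients).
#' @param params a [segmentation_params()] object.
#' @return The retained rows, same columns.
#' @export
filter_segments <- function(segments, params = segmentation_params()) {
  if (!nrow(segments)) return(segments)
  if (!"q_value" %in% names(segments)) stop("segments must carry q_value")
  keep <- segments$state != "neutral" &
    segments$q_value <= params$max_fdr &
    (segments$end - segments$start) >= params$min_length_bp &
    segments$n_probes >= params$min_probes
  segments[keep, , drop = FALSE]
}

#' Segment and filter every patient of a log-ratio matrix
#'
#' @param probe_map probe annotation (`probe`, `chrom`, `pos`), sorted.
#' @param log_ratios probe x patient matrix.
#' @param params a [segmentation_params()] object.
#' @param filter if `TRUE` (default) returns only filtered CNAs.
#' @return Data frame of segments across all patients.
#' @export
segment_cohort <- function(probe_map, log_ratios,
                           params = segmentation_params(), filter = TRUE) {
  stopifnot(nrow(probe_map) == nrow(log_ratios))
  res <- lapply(colnames(log_ratios), function(p) {
    seg <- segment_profile(probe_map, log_ratios[, p], params, patient = p)
    if (filter) filter_segments(seg, params) else seg
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## Carrier threshold: at least ceil(fraction * n) patients, never below 1.
## The tiny epsilon guards against 0.1 * 10 evaluating just above 1 in
## floating point.
recurrence_threshold <- function(recurrence_fraction, n_patients) {
  max(1L, as.integer(ceiling(recurrence_fraction * n_patients - 1e-9)))
}

#' Detect recurrent CNA regions across patients
#'
#' Counts, at every probe, the number of patients whose filtered CNAs overlap
#' it (direction-agnostic), and reports maximal probe runs where the count
#' reaches `ceil(recurrence_fraction * n_patients)`. Each region records its
#' carriers and, per carrier, the direction of the overlapping CNA.
#'
#' @param cnas filtered CNA data frame (from [segment_cohort()] or
#'   [filter_segments()] rows pooled over patients).
#' @param n_patients cohort size the recurrence fraction refers to.
#' @param probe_map probe annotation (`probe`, `chrom`, `pos`), sorted.
#' @param recurrence_fraction minimum altered fraction (default 0.10).
#'
#' @return A list with `regions` (data frame: `region_id`, `chrom`, `start`,
#'   `end`, `n_probes`, `n_carriers`) and `carriers` (data frame: `region_id`,
#'   `patient`, `direction`).
#' @export
detect_recurrent_regions <- function(cnas, n_patients, probe_map,
                                     recurrence_fraction = 0.10) {
  thr <- recurrence_threshold(recurrence_fraction, n_patients)
  empty <- list(
    regions = data.frame(region_id = integer(), chrom = character(),
                         start = numeric(), end = numeric(),
                         n_probes = integer(), n_carriers = integer(),
                         stringsAsFactors = FALSE),
    carriers = data.frame(region_id = integer(), patient = character(),
                          direction = character(), stringsAsFactors = FALSE),
    threshold = thr)
  if (is.null(cnas) || !nrow(cnas)) return(empty)

  counts <- integer(nrow(probe_map))
  cna_rows <- vector("list", nrow(cnas))
  for (i in seq_len(nrow(cnas))) {
    rows <- which(probe_map$chrom == cnas$chrom[i] &
                    probe_map$pos >= cnas$start[i] &
                    probe_map$pos < cnas$end[i])
    cna_rows[[i]] <- rows
    counts[rows] <- counts[rows] + 1L
  }

  regions <- list()
  carriers <- list()
  rid <- 0L
  for (ch in unique(probe_map$chrom)) {
    rows <- which(probe_map$chrom == ch)
    hit <- counts[rows] >= thr
    if (!any(hit)) next
    r <- rle(hit)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in which(r$values)) {
      rid <- rid + 1L
      seg_rows <- rows[run_start[k]:run_end[k]]
      reg_start <- probe_map$pos[seg_rows[1]]
      reg_end <- probe_map$pos[seg_rows[length(seg_rows)]] + 1L
      ov <- which(cnas$chrom == ch & cnas$start < reg_end & cnas$end > reg_start)
      ## direction per patient: overlapping CNA with the most covered probes
      ov_n <- vapply(ov, function(i) length(intersect(cna_rows[[i]], seg_rows)),
                     integer(1))
      ov <- ov[ov_n > 0]; ov_n <- ov_n[ov_n > 0]
      pat <- cnas$patient[ov]
      dir <- vapply(unique(pat), function(p) {
        sel <- pat == p
        cnas$state[ov[sel][which.max(ov_n[sel])]]
      }, character(1))
      regions[[rid]] <- data.frame(
        region_id = rid, chrom = ch, start = reg_start, end = reg_end,
        n_probes = length(seg_rows), n_carriers = length(unique(pat)),
        stringsAsFactors = FALSE)
      carriers[[rid]] <- data.frame(
        region_id = rid, patient = unique(pat), direction = dir,
        stringsAsFactors = FALSE)
    }
  }
  if (!rid) return(empty)
  list(regions = do.call(rbind, regions),
       carriers = do.call(rbind, carriers),
       threshold = thr)
}

#' Tumour/normal label-reversal QC from the MYCN locus
#'
#' For a patient clinically flagged as MYCN-amplified, the aCGH profile should
#' show a gain over the MYCN locus; a clear loss there suggests the tumour and
#' reference channels were swapped. Flips of all probe signs clear the flag.
#'
#' @param probe_map probe annotation (`probe`, `chrom`, `pos`).
#' @param log_ratios per-probe log2 ratios for one patient.
#' @param mycn_amplified logical clinical amplification flag.
#' @param mycn_locus list with `chrom`, `start`, `end` of the locus.
#' @param params a [segmentation_params()] (supplies `loss_threshold`).
#' @param min_probes minimum probes required over the locus.
#'
#' @return List with `status` (`"flagged"`, `"not_flagged"` or
#'   `"undetermined"`), `flagged` (logical, `NA` when undetermined),
#'   `evidence` (`-mean_lr` over the locus when flagged, else `NA`) and
#'   `locus_mean_lr`.
#' @export
detect_label_reversal <- function(probe_map, log_ratios, mycn_amplified,
                                  mycn_locus, params = segmentation_params(),
                                  min_probes = 10) {
  rows <- which(probe_map$chrom == mycn_locus$chrom &
                  probe_map$pos >= mycn_locus$start &
                  probe_map$pos < mycn_locus$end)
  if (length(rows) < min_probes) {
    return(list(status = "undetermined", flagged = NA,
                evidence = NA_real_, locus_mean_lr = NA_real_))
  }
  m <- mean(log_ratios[rows])
  flagged <- isTRUE(mycn_amplified) && m <= params$loss_threshold
  list(status = if (flagged) "flagged" else "not_flagged",
       flagged = flagged,
       evidence = if (flagged) -m else NA_real_,
       locus_mean_lr = m)
}
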