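#' Configuration for a synthetic multi-omics cohort
#'
#' Defines the generative model for [generate_cohort()]: a cohort of tumour
#' patients with probe-level copy-number log-ratios carrying planted recurrent
#' gain/loss regions, FPKM-like expression with cis dosage effects on planted
#' driver genes and trans effects on their network neighbours, a scale-free
#' interaction network with the drivers wired as hubs, and survival times whose
#' hazard increases with each patient's planted driver burden.
#'
#' @param n_patients number of patients.
#' @param n_genes number of genes (network nodes, expression rows).
#' @param n_chromosomes chromosomes the genes are spread over.
#' @param probes_per_gene aCGH probes placed inside each gene body.
#' @param n_planted_regions number of recurrent CNA regions to plant.
#' @param planted_region_gene_span consecutive genes covered by each region.
#' @param planted_carrier_fraction fraction of patients carrying each region,
#'   in (0, 1].
#' @param gain_shift,loss_shift log2-ratio shift added to carrier probes of a
#'   gain (resp. loss) region.
#' @param probe_noise_sd Gaussian probe noise, log2-ratio units.
#' @param n_planted_drivers number of planted driver genes, placed inside
#'   planted regions (at most one per region before wrapping around).
#' @param cis_effect expression shift (in within-patient standard deviations of
#'   the log2 scale) applied to an altered planted driver in its carriers,
#'   sign-matched to the alteration direction.
#' @param bystander_cis_effect same dosage shift applied to the non-driver
#'   genes of a planted region in its carriers; default 0 so that planted
#'   drivers are the only cis-responsive genes.
#' @param trans_effect expression shift applied to a driver's planted network
#'   targets in that driver's carriers.
#' @param neighbor_fanout planted driver-target edges per driver.
#' @param network_attachment edges added per node in preferential-attachment
#'   network growth.
#' @param baseline_hazard baseline event hazard, per day.
#' @param log_hr_per_driver log hazard ratio per planted driver carried.
#' @param censor_rate target fraction of patients censored (uniform
#'   administrative censoring).
#' @param mixed_direction_regions number of planted regions whose carriers are
#'   split between gain and loss (for testing the direction-purity rule).
#' @param mycn_linked_region if `TRUE`, the MYCN-analogue amplification flag in
#'   the clinical table is set for carriers of the first planted gain region
#'   (for label-reversal QC tests) instead of being drawn independently.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   configuration.
#'
#' @return An object of class `synth_config` (a named list).
#' @export
synth_config <- function(n_patients = 48,
                         n_genes = 2000,
                         n_chromosomes = 10,
                         probes_per_gene = 1,
                         n_planted_regions = 10,
                         planted_region_gene_span = 20,
                         planted_carrier_fraction = 0.25,
                         gain_shift = 0.5,
                         loss_shift = -0.5,
                         probe_noise_sd = 0.1,
                         n_planted_drivers = 10,
                         cis_effect = 2,
                         bystander_cis_effect = 0,
                         trans_effect = 1.5,
                         neighbor_fanout = 15,
                         network_attachment = 2,
                         baseline_hazard = 1 / 2000,
                         log_hr_per_driver = log(2.7),
                         censor_rate = 0.3,
                         mixed_direction_regions = 0,
                         mycn_linked_region = FALSE,
                         seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_patients", "n_genes", "n_chromosomes", "probes_per_gene",
              "n_planted_regions", "planted_region_gene_span",
              "network_attachment")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("invalid-config: `", nm, "` must be a positive integer", call. = FALSE)
    }
  }
  if (n_planted_drivers < 0 ||
      n_planted_drivers > n_planted_regions * planted_region_gene_span) {
    stop("invalid-config: n_planted_drivers must lie in [0, regions x span]",
         call. = FALSE)
  }
  if (planted_carrier_fraction <= 0 || planted_carrier_fraction > 1) {
    stop("invalid-config: planted_carrier_fraction must be in (0, 1]", call. = FALSE)
  }
  if (planted_carrier_fraction * n_patients < 1) {
    stop("invalid-config: planted_carrier_fraction x n_patients must be >= 1",
         call. = FALSE)
  }
  if (neighbor_fanout >= n_genes) {
    stop("invalid-config: neighbor_fanout must be < n_genes", call. = FALSE)
  }
  if (gain_shift <= 0 || loss_shift >= 0) {
    stop("invalid-config: gain_shift > 0 > loss_shift required", call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("invalid-config: censor_rate must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Generate a scale-free interaction network with planted driver hubs
#'
#' Grows an undirected preferential-attachment graph over `n_genes` nodes and
#' then wires each planted driver to `neighbor_fanout` additional distinct
#' target genes; the targets are recorded so downstream tests can check that
#' trans expression effects land on true network neighbours.
#'
#' @param n_genes number of nodes; node names are the gene ids.
#' @param network_attachment edges added per new node during growth.
#' @param planted_drivers character vector of driver gene ids (may be empty).
#' @param neighbor_fanout extra targets wired to each planted driver.
#' @param seed integer seed.
#' @param gene_ids optional explicit node names (length `n_genes`).
#'
#' @return A list with `graph` (an [igraph][igraph::igraph-package] object, no
#'   self-loops or multi-edges) and `driver_targets` (named list of character
#'   target vectors per planted driver).
#' @export
generate_network <- function(n_genes, network_attachment = 2,
                             planted_drivers = character(),
                             neighbor_fanout = 0, seed = 1L,
                             gene_ids = NULL) {
  if (n_genes < network_attachment + 1) {
    stop("invalid-config: n_genes must be >= network_attachment + 1", call. = FALSE)
  }
  if (neighbor_fanout >= n_genes) {
    stop("invalid-config: neighbor_fanout must be < n_genes", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- default_gene_ids(n_genes)
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
  set.seed(seed)
  g <- igraph::sample_pa(n_genes, power = 1, m = network_attachment,
                         directed = FALSE)
  igraph::V(g)$name <- gene_ids
  g <- igraph::simplify(g)

  driver_targets <- list()
  for (d in planted_drivers) {
    if (!d %in% gene_ids) stop("planted driver not among gene ids: ", d)
    current <- igraph::neighbors(g, d)$name
    pool <- setdiff(gene_ids, c(d, current))
    n_new <- min(neighbor_fanout, length(pool))
    new_targets <- if (n_new > 0) sample(pool, n_new) else character()
    targets <- c(current[seq_len(min(length(current),
                                     neighbor_fanout - n_new))], new_targets)
    if (n_new > 0) {
      g <- igraph::add_edges(g, as.vector(rbind(d, new_targets)))
    }
    driver_targets[[d]] <- targets
  }
  g <- igraph::simplify(g)
  list(graph = g, driver_targets = driver_targets)
}

default_gene_ids <- function(n) sprintf("g%05d", seq_len(n))
default_patient_ids <- function(n) sprintf("P%03d", seq_len(n))

# Gene body length and spacing used by the synthetic genome (bp).
.GENE_LEN <- 10000L
.GENE_SPACING <- 100000L

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates, deterministically from `config$seed`: (i) a genome annotation
#' and probe map; (ii) probe log-ratios where carriers of a planted region get
#' the configured gain/loss shift plus Gaussian noise and non-carriers noise
#' only; (iii) FPKM-like expression from per-gene lognormal baselines with cis
#' dosage effects on altered planted drivers and trans effects on their
#' planted network targets; (iv) exponential survival times with hazard
#' `baseline_hazard * exp(log_hr_per_driver * driver_count)` and uniform
#' administrative censoring; and (v) clinical covariates (age, INSS stage,
#' MYCN-analogue amplification) drawn independently of driver burden unless
#' `mycn_linked_region` is set.
#'
#' @param config a [synth_config()] object.
#'
#' @return An object of class `synthetic_cohort`: a list with
#'   `gene_annotation` (gene, chrom, start, end; 0-based half-open),
#'   `probe_map` (probe, chrom, pos), `log_ratios` (probe x patient matrix),
#'   `expression` (gene x patient FPKM matrix), `network` (igraph),
#'   `driver_targets`, `clinical` (patient, os_days, os_event, age_days,
#'   stage, mycn_amp, high_risk), and `truth` (planted regions with carriers
#'   and directions, planted drivers, per-patient driver counts).
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_p <- config$n_patients
  n_g <- config$n_genes
  patients <- default_patient_ids(n_p)
  genes <- default_gene_ids(n_g)

  ## genome layout: genes round-robin balanced across chromosomes, laid out
  ## consecutively with fixed spacing
  per_chrom <- rep(floor(n_g / config$n_chromosomes), config$n_chromosomes)
  extra <- n_g - sum(per_chrom)
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom <- rep(sprintf("chr%d", seq_len(config$n_chromosomes)), per_chrom)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len))
  start <- (idx_in_chrom - 1L) * .GENE_SPACING
  gene_annotation <- data.frame(gene = genes, chrom = chrom, start = start,
                                end = start + .GENE_LEN,
                                stringsAsFactors = FALSE)

  ppg <- config$probes_per_gene
  probe_pos <- rep(start, each = ppg) +
    rep(round((seq_len(ppg) - 0.5) / ppg * .GENE_LEN), times = n_g)
  probe_map <- data.frame(
    probe = sprintf("pr%06d", seq_len(n_g * ppg)),
    chrom = rep(chrom, each = ppg),
    pos = as.integer(probe_pos),
    gene = rep(genes, each = ppg),
    stringsAsFactors = FALSE)

  ## plant regions: round-robin over chromosomes, non-overlapping, separated
  ## by a full span of unaltered genes
  span <- config$planted_region_gene_span
  n_r <- config$n_planted_regions
  region_chrom <- ((seq_len(n_r) - 1L) %% config$n_chromosomes) + 1L
  slot <- stats::ave(seq_len(n_r), region_chrom, FUN = seq_along)
  first_idx <- (slot - 1L) * 2L * span + 1L
  if (any(first_idx + span - 1L > per_chrom[region_chrom])) {
    stop("invalid-config: planted regions exceed chromosome capacity", call. = FALSE)
  }
  chrom_offset <- c(0L, cumsum(per_chrom))[region_chrom]
  region_genes <- lapply(seq_len(n_r), function(r) {
    genes[chrom_offset[r] + first_idx[r] + seq_len(span) - 1L]
  })
  direction <- rep(c("gain", "loss"), length.out = n_r)
  n_carriers <- max(1L, round(config$planted_carrier_fraction * n_p))
  carriers <- lapply(seq_len(n_r), function(r) sort(sample(patients, n_carriers)))
  ## per-carrier direction; mixed regions split their carriers between both
  carrier_dir <- lapply(seq_len(n_r), function(r) {
    d <- rep(direction[r], n_carriers)
    if (r <= config$mixed_direction_regions && n_carriers >= 2) {
      flip <- seq_len(floor(n_carriers / 2))
      d[flip] <- setdiff(c("gain", "loss"), direction[r])
    }
    stats::setNames(d, carriers[[r]])
  })

  ## planted drivers: middle gene of each region, wrapping with offsets if
  ## more drivers than regions are requested
  n_d <- config$n_planted_drivers
  drivers <- character(0)
  if (n_d > 0) {
    reg_of_driver <- ((seq_len(n_d) - 1L) %% n_r) + 1L
    rank_within <- stats::ave(seq_len(n_d), reg_of_driver, FUN = seq_along)
    drivers <- vapply(seq_len(n_d), function(i) {
      rg <- region_genes[[reg_of_driver[i]]]
      pick <- ((ceiling(span / 2) + rank_within[i] - 2L) %% span) + 1L
      rg[pick]
    }, character(1))
    names(reg_of_driver) <- drivers
  } else {
    reg_of_driver <- integer(0)
  }

  net <- generate_network(n_g, config$network_attachment,
                          planted_drivers = drivers,
                          neighbor_fanout = config$neighbor_fanout,
                          seed = sample.int(.Machine$integer.max, 1),
                          gene_ids = genes)

  ## probe log-ratios
  lr <- matrix(stats::rnorm(nrow(probe_map) * n_p, 0, config$probe_noise_sd),
               nrow = nrow(probe_map), ncol = n_p,
               dimnames = list(probe_map$probe, patients))
  shift_of <- c(gain = config$gain_shift, loss = config$loss_shift)
  for (r in seq_len(n_r)) {
    rows <- probe_map$gene %in% region_genes[[r]]
    for (p in carriers[[r]]) {
      lr[rows, p] <- lr[rows, p] + shift_of[[carrier_dir[[r]][[p]]]]
    }
  }

  ## expression: lognormal baseline on the FPKM scale, effects added on the
  ## log2(FPKM + 1) scale in units of each patient's cross-gene SD
  meanlog <- stats::rnorm(n_g, mean = 2, sd = 1.2)
  fpkm <- matrix(stats::rlnorm(n_g * n_p, meanlog = rep(meanlog, n_p), sdlog = 0.6),
                 nrow = n_g, ncol = n_p, dimnames = list(genes, patients))
  l2 <- log2(fpkm + 1)
  sd_p <- apply(l2, 2, stats::sd)
  sgn <- c(gain = 1, loss = -1)
  add_effect <- function(l2, gene_set, patient, amount) {
    l2[gene_set, patient] <- l2[gene_set, patient] + amount
    l2
  }
  for (r in seq_len(n_r)) {
    r_drivers <- drivers[reg_of_driver == r]
    bystanders <- setdiff(region_genes[[r]], r_drivers)
    for (p in carriers[[r]]) {
      s <- sgn[[carrier_dir[[r]][[p]]]]
      if (config$cis_effect != 0 && length(r_drivers)) {
        l2 <- add_effect(l2, r_drivers, p, s * config$cis_effect * sd_p[p])
      }
      if (config$bystander_cis_effect != 0 && length(bystanders)) {
        l2 <- add_effect(l2, bystanders, p, s * config$bystander_cis_effect * sd_p[p])
      }
      if (config$trans_effect != 0 && length(r_drivers)) {
        for (d in r_drivers) {
          tg <- net$driver_targets[[d]]
          if (length(tg)) {
            l2 <- add_effect(l2, tg, p, s * config$trans_effect * sd_p[p])
          }
        }
      }
    }
  }
  expression <- pmax(2 ^ l2 - 1, 0)

  ## planted driver burden and survival
  driver_count <- stats::setNames(integer(n_p), patients)
  for (d in drivers) {
    for (p in carriers[[reg_of_driver[[d]]]]) {
      driver_count[p] <- driver_count[p] + 1L
    }
  }
  hazard <- config$baseline_hazard * exp(config$log_hr_per_driver * driver_count)
  event_t <- stats::rexp(n_p, rate = hazard)
  if (config$censor_rate > 0) {
    ## administrative horizon tuned so the expected censored fraction matches
    cens_frac <- function(tau) mean((1 - exp(-hazard * tau)) / (hazard * tau))
    tau <- stats::uniroot(function(x) cens_frac(x) - config$censor_rate,
                          lower = 1, upper = 1e9, tol = 1e-6)$root
    cens_t <- stats::runif(n_p, 0, tau)
    os_days <- pmin(event_t, cens_t)
    os_event <- as.integer(event_t <= cens_t)
  } else {
    os_days <- event_t
    os_event <- rep(1L, n_p)
  }
  os_days <- as.integer(pmax(1, ceiling(os_days)))

  mycn_amp <- stats::rbinom(n_p, 1, 0.2)
  if (config$mycn_linked_region) {
    gain_regions <- which(direction == "gain")
    linked <- if (length(gain_regions)) gain_regions[1] else 1L
    mycn_amp <- as.integer(patients %in% carriers[[linked]])
  }
  clinical <- data.frame(
    patient = patients,
    os_days = os_days,
    os_event = os_event,
    age_days = as.integer(pmax(1, round(stats::rlnorm(n_p, log(500), 1)))),
    stage = sample(c("1", "2", "3", "4", "4S"), n_p, replace = TRUE,
                   prob = c(0.05, 0.05, 0.10, 0.60, 0.20)),
    mycn_amp = mycn_amp,
    high_risk = 1L,
    stringsAsFactors = FALSE)

  region_start <- vapply(region_genes, function(g) {
    min(gene_annotation$start[match(g, genes)])
  }, numeric(1))
  region_end <- vapply(region_genes, function(g) {
    max(gene_annotation$end[match(g, genes)])
  }, numeric(1))
  truth <- list(
    planted_regions = data.frame(
      region_id = seq_len(n_r),
      chrom = sprintf("chr%d", region_chrom),
      start = region_start, end = region_end,
      direction = direction,
      n_carriers = n_carriers,
      stringsAsFactors = FALSE),
    region_genes = region_genes,
    region_carriers = carriers,
    region_carrier_direction = carrier_dir,
    planted_drivers = drivers,
    driver_region = if (length(drivers)) reg_of_driver else integer(0),
    driver_targets = net$driver_targets,
    per_patient_driver_count = driver_count)

  structure(list(
    config = config,
    gene_annotation = gene_annotation,
    probe_map = probe_map[, c("probe", "chrom", "pos")],
    log_ratios = lr,
    expression = expression,
    network = net$graph,
    driver_targets = net$driver_targets,
    clinical = clinical,
    truth = truth), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", ncol(x$log_ratios), "patients,",
      nrow(x$expression), "genes,", nrow(x$log_ratios), "probes,",
      igraph::ecount(x$network), "network edges\n")
  cat("  planted:", nrow(x$truth$planted_regions), "regions,",
      length(x$truth$planted_drivers), "drivers\n")
  invisible(x)
}
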