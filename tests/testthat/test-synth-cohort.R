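test_that("preferential-attachment network has expected structure and planted hubs", {
  # attachment 1, no drivers: a tree on n nodes has n - 1 edges
  net <- generate_network(10, network_attachment = 1, seed = 3)
  expect_equal(igraph::ecount(net$graph), 9)
  expect_true(igraph::is_connected(net$graph))

  # planted driver gets at least its fanout of neighbours, recorded as targets
  ids <- sprintf("g%05d", 1:200)
  net <- generate_network(200, 2, planted_drivers = c("g00050", "g00120"),
                          neighbor_fanout = 12, seed = 7)
  for (d in c("g00050", "g00120")) {
    expect_gte(igraph::degree(net$graph, d), 12)
    expect_length(net$driver_targets[[d]], 12)
    expect_true(all(net$driver_targets[[d]] %in%
                      igraph::neighbors(net$graph, d)$name))
  }
  # simple graph: no loops, no multi-edges
  expect_true(igraph::is_simple(net$graph))

  # determinism
  e1 <- igraph::as_edgelist(generate_network(300, 2, seed = 11)$graph)
  e2 <- igraph::as_edgelist(generate_network(300, 2, seed = 11)$graph)
  expect_identical(e1, e2)

  expect_error(generate_network(10, 2, neighbor_fanout = 10), "invalid-config")
  expect_error(generate_network(2, 5), "invalid-config")
})

test_that("cohort generation is deterministic and internally consistent", {
  cfg <- small_config(seed = 5)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$log_ratios, co2$log_ratios)
  expect_identical(co1$expression, co2$expression)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(igraph::as_edgelist(co1$network),
                   igraph::as_edgelist(co2$network))

  co <- co1
  # consistent patient ordering everywhere
  expect_identical(colnames(co$log_ratios), co$clinical$patient)
  expect_identical(colnames(co$expression), co$clinical$patient)
  expect_true(all(co$clinical$os_days > 0))
  expect_true(all(co$expression >= 0))

  # every planted driver lies inside exactly one planted region
  tr <- co$truth
  for (i in seq_along(tr$planted_drivers)) {
    hits <- vapply(tr$region_genes,
                   function(g) tr$planted_drivers[i] %in% g, logical(1))
    expect_equal(sum(hits), 1)
    expect_equal(unname(which(hits)), unname(tr$driver_region[i]))
  }
  # carrier counts match the configured fraction (within rounding)
  expect_equal(unique(vapply(tr$region_carriers, length, integer(1))),
               round(0.25 * 24))
  # per-patient driver counts match region carriage
  recount <- stats::setNames(integer(24), co$clinical$patient)
  for (d in tr$planted_drivers) {
    for (p in tr$region_carriers[[tr$driver_region[[d]]]]) {
      recount[p] <- recount[p] + 1L
    }
  }
  expect_identical(recount, tr$per_patient_driver_count)
})

test_that("carrier log-ratio means converge to the planted shift", {
  # Monte-Carlo check against the generating distribution: with sd 0.05 and
  # >= 100 probes per planted region, the carrier mean inside the region is
  # within +/-0.05 of the +0.5 shift
  cfg <- synth_config(n_patients = 12, n_genes = 400, n_chromosomes = 2,
                      probes_per_gene = 5, n_planted_regions = 2,
                      planted_region_gene_span = 25, n_planted_drivers = 2,
                      probe_noise_sd = 0.05, planted_carrier_fraction = 0.5,
                      neighbor_fanout = 5, seed = 9)
  co <- generate_cohort(cfg)
  tr <- co$truth
  pm <- generate_cohort(cfg)$probe_map
  for (r in 1:2) {
    reg <- tr$planted_regions[r, ]
    rows <- pm$chrom == reg$chrom & pm$pos >= reg$start & pm$pos < reg$end
    expect_gte(sum(rows), 100)
    shift <- if (reg$direction == "gain") 0.5 else -0.5
    for (p in tr$region_carriers[[r]]) {
      expect_lt(abs(mean(co$log_ratios[rows, p]) - shift), 0.05)
    }
    non <- setdiff(co$clinical$patient, tr$region_carriers[[r]])
    expect_lt(max(abs(colMeans(co$log_ratios[rows, non]))), 0.05)
  }
})

test_that("null configurations carry no expression or survival signal", {
  # cis = trans = 0: a planted driver's expression is independent of copy
  # number; two-sample p-values approximately uniform across seeds
  pvals <- vapply(1:12, function(s) {
    co <- generate_cohort(small_config(seed = 600 + s, cis_effect = 0,
                                       trans_effect = 0))
    tr <- co$truth
    d <- tr$planted_drivers[1]
    car <- tr$region_carriers[[tr$driver_region[[d]]]]
    non <- setdiff(co$clinical$patient, car)
    stats::t.test(co$expression[d, car], co$expression[d, non])$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # zero hazard effect: planted burden does not separate survival
  ps <- vapply(1:12, function(s) {
    co <- generate_cohort(small_config(seed = 700 + s, log_hr_per_driver = 0))
    burden <- co$truth$per_patient_driver_count
    grp <- data.frame(patient = names(burden),
                      group = factor(ifelse(burden > stats::median(burden),
                                            "high", "low"),
                                     levels = c("low", "high")))
    suppressWarnings(km_logrank(grp, co$clinical)$p)
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("trans-wired targets are over-represented among carriers' extreme genes", {
  co <- generate_cohort(small_config(seed = 77))
  expr <- preprocess_expression(co$expression)
  tr <- co$truth
  d <- tr$planted_drivers[1]
  targets <- tr$driver_targets[[d]]
  carriers <- tr$region_carriers[[tr$driver_region[[d]]]]
  hit_rate <- mean(vapply(carriers, function(p) {
    ags <- build_patient_ags(expr, p, top_n = 50)
    mean(targets %in% ags$gene)
  }, numeric(1)))
  # 100-gene AGS out of 600 genes would catch ~17% of a random set
  expect_gt(hit_rate, 0.4)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synth_config(n_patients = 0), "invalid-config")
  expect_error(synth_config(planted_carrier_fraction = 0), "invalid-config")
  expect_error(synth_config(n_patients = 10, planted_carrier_fraction = 0.05),
               "invalid-config")
  expect_error(synth_config(n_planted_drivers = 1000, n_planted_regions = 2,
                            planted_region_gene_span = 10), "invalid-config")
  expect_error(synth_config(neighbor_fanout = 5000), "invalid-config")
  # planted regions exceeding chromosome capacity
  expect_error(generate_cohort(synth_config(n_genes = 100, n_chromosomes = 1,
                                            n_planted_regions = 5,
                                            planted_region_gene_span = 20,
                                            n_planted_drivers = 1,
                                            neighbor_fanout = 3)),
               "invalid-config")
})
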