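toy_calls <- function() {
  alt <- data.frame(
    gene = c("g", "g", "h", "x"),
    patient = c("P1", "P3", "P2", "P4"),
    state = "gain", stringsAsFactors = FALSE)
  fgs <- fake_fgs(c("g", "h", "x"), alt)
  common <- data.frame(gene = "g", scope = "common", stringsAsFactors = FALSE)
  patient <- data.frame(gene = "h", scope = "P2", stringsAsFactors = FALSE)
  list(fgs = fgs, common = common, patient = patient,
       patients = sprintf("P%d", 1:5))
}

test_that("DGscore counts carried drivers per patient, by mode", {
  tc <- toy_calls()
  sc <- compute_dgscore(tc$common, tc$patient, tc$fgs, tc$patients)
  # common driver g carried by P1 and P3; patient-specific h for P2
  expect_equal(sc$dgscore, c(1, 1, 1, 0, 0))
  expect_equal(sc$drivers[1:3], c("g", "h", "g"))

  co <- compute_dgscore(tc$common, tc$patient, tc$fgs, tc$patients,
                        mode = "common_only")
  ps <- compute_dgscore(tc$common, tc$patient, tc$fgs, tc$patients,
                        mode = "patient_specific_only")
  raw <- compute_dgscore(tc$common, tc$patient, tc$fgs, tc$patients,
                         mode = "raw_fgs")
  expect_equal(co$dgscore, c(1, 0, 1, 0, 0))
  expect_equal(ps$dgscore, c(0, 1, 0, 0, 0))
  # raw mode ignores the network filter: x counts for P4
  expect_equal(raw$dgscore, c(1, 1, 1, 1, 0))
  # union bound: the all-mode score dominates both restricted modes
  expect_true(all(sc$dgscore >= pmax(co$dgscore, ps$dgscore)))

  bad <- data.frame(gene = "h", scope = "P99", stringsAsFactors = FALSE)
  expect_error(compute_dgscore(tc$common, bad, tc$fgs, tc$patients),
               "unknown patient")
  none <- compute_dgscore(tc$common[0, ], tc$patient[0, ], tc$fgs, tc$patients)
  expect_equal(none$dgscore, rep(0, 5))
})

test_that("median split sends strictly-greater-than-median scores high", {
  s <- data.frame(patient = sprintf("P%d", 1:4), dgscore = c(0, 1, 2, 3))
  g <- median_split(s)
  expect_equal(as.character(g$group), c("low", "low", "high", "high"))
  s2 <- data.frame(patient = sprintf("P%d", 1:4), dgscore = c(1, 1, 1, 5))
  g2 <- median_split(s2)
  expect_equal(sum(g2$group == "high"), 1)
  expect_equal(g2$patient[g2$group == "high"], "P4")
  s3 <- data.frame(patient = sprintf("P%d", 1:4), dgscore = rep(2, 4))
  expect_error(median_split(s3), "degenerate-split")
})

test_that("log-rank test matches a hand-computed table and its invariances", {
  # 6 patients, complete separation: group A events at 1, 2, 3; B censored at 10
  clin <- data.frame(patient = sprintf("P%d", 1:6),
                     os_days = c(1, 2, 3, 10, 10, 10),
                     os_event = c(1, 1, 1, 0, 0, 0))
  grp <- data.frame(patient = clin$patient,
                    group = factor(rep(c("high", "low"), each = 3),
                                   levels = c("low", "high")))
  res <- suppressWarnings(km_logrank(grp, clin))
  # hand computation: O - E = 3 - (3/6 + 2/5 + 1/4); V = sum of
  # n1 n2 d (n - d) / (n^2 (n - 1)) over the three event times
  OE <- 3 - (3 / 6 + 2 / 5 + 1 / 4)
  V <- 3 * 3 * 1 * 5 / (36 * 5) + 2 * 3 * 1 * 4 / (25 * 4) + 1 * 3 * 1 * 3 / (16 * 3)
  expect_equal(res$chisq, OE^2 / V, tolerance = 1e-12)
  expect_warning(km_logrank(grp, clin), "zero events")

  # invariant under patient reordering
  idx <- c(4, 2, 6, 1, 3, 5)
  res2 <- suppressWarnings(km_logrank(grp[idx, ], clin))
  expect_equal(res2$chisq, res$chisq)

  # identical survival in both groups: statistic 0, p = 1
  clin3 <- data.frame(patient = sprintf("P%d", 1:6),
                      os_days = rep(c(5, 9, 13), 2),
                      os_event = rep(1, 6))
  res3 <- km_logrank(grp, clin3)
  expect_equal(res3$chisq, 0, tolerance = 1e-12)
  expect_equal(res3$p, 1, tolerance = 1e-12)

  expect_error(km_logrank(grp, clin[1:4, ]), "missing survival")
})

test_that("Cox models reproduce an analytic partial-likelihood solution", {
  # two groups of two, event times 1 and 4 (x = 1) vs 2 and 3 (x = 0):
  # the score equation reduces to u^2 + u - 1 = 0, u = exp(beta),
  # so HR = (sqrt(5) - 1) / 2
  clin <- data.frame(patient = sprintf("P%d", 1:4),
                     os_days = c(1, 4, 2, 3), os_event = 1,
                     age_days = c(100, 200, 300, 400),
                     stage = c("4", "1", "4", "1"),
                     mycn_amp = c(0, 1, 0, 1), high_risk = 1,
                     stringsAsFactors = FALSE)
  scores <- data.frame(patient = clin$patient, dgscore = c(5, 5, 0, 0),
                       group = factor(c("high", "high", "low", "low"),
                                      levels = c("low", "high")))
  cx <- cox_models(scores, clin)
  hr <- cx$hazard_ratio[cx$model_id == "1a" & cx$variable == "DGscore"]
  expect_equal(hr, (sqrt(5) - 1) / 2, tolerance = 1e-6)
  # all nine model specifications are reported
  expect_setequal(unique(cx$model_id), c("1a", "1b", "1c", "1d", "2", "3",
                                         "4", "5", "6"))
  # continuous coding scales the same fit: exp(5 * beta_binary) when scores
  # are 5 vs 0
  cxc <- cox_models(scores, clin, dgscore_as = "continuous")
  hrc <- cxc$hazard_ratio[cxc$model_id == "1a" & cxc$variable == "DGscore"]
  expect_equal(hrc^5, hr, tolerance = 1e-6)

  # constant covariate is flagged non-identifiable, pipeline continues
  clin2 <- transform(clin, mycn_amp = 1)
  cx2 <- cox_models(scores, clin2)
  expect_equal(unique(cx2$note[cx2$variable == "MYCN amplification"]),
               "non-identifiable")
  expect_true(any(cx2$note == "ok"))
})

test_that("single-gene expression split runs the comparator analysis", {
  set.seed(17)
  v <- matrix(rlnorm(60 * 8, 2, 1), 60, 8,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("P%d", 1:8)))
  clin <- data.frame(patient = sprintf("P%d", 1:8),
                     os_days = sample(100:900, 8), os_event = 1)
  expr <- preprocess_expression(v)
  res <- suppressWarnings(single_gene_split(expr, "g05", clin))
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(sum(res$groups$group == "high"), 4)
  expect_error(single_gene_split(expr, "nope", clin), "not in expression")
})
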