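test_that("expression preprocessing standardises within patient and ranks across patients", {
  set.seed(10)
  v <- matrix(rlnorm(50 * 6, 2, 1), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("P%d", 1:6)))
  expr <- preprocess_expression(v)
  expect_equal(unname(colMeans(expr$scaled)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(expr$scaled, 2, sd)), rep(1, 6), tolerance = 1e-12)

  # a gene with values 1, 10, 100 across patients ranks 1, 2, 3 after log scaling
  v3 <- matrix(rlnorm(30 * 3, 2, 1), 30, 3,
               dimnames = list(sprintf("g%02d", 1:30), c("A", "B", "C")))
  v3["g01", ] <- c(1, 10, 100)
  r <- preprocess_expression(v3)$ranks["g01", ]
  expect_equal(unname(r), c(1, 2, 3))

  # every gene's ranks are a permutation of 1..n_patients up to ties
  expect_true(all(rowSums(preprocess_expression(v3)$ranks) == 6))
  # a gene whose standardised values are tied gets the mid-rank everywhere
  sc <- rbind(flat = c(0, 0, 0), var = c(-1, 0, 1))
  colnames(sc) <- c("A", "B", "C")
  expect_equal(unname(fake_expr(sc)$ranks["flat", ]), rep(2, 3))

  # a zero-variance patient column is degenerate input
  vbad <- v; vbad[, 2] <- 7
  expect_error(preprocess_expression(vbad), "degenerate")
  expect_error(preprocess_expression(v - 10), "negative")
})

test_that("genes map to regions by >= 1 bp overlap with half-open intervals", {
  ann <- data.frame(gene = c("a", "b", "c"), chrom = "chr1",
                    start = c(100, 100, 500), end = c(200, 200, 600))
  reg <- data.frame(region_id = 1:2, chrom = "chr1",
                    start = c(150, 200), end = c(300, 300))
  m <- annotate_regions(reg, ann)
  expect_true(any(m$region_id == 1 & m$gene == "a"))   # [100,200) vs [150,300)
  expect_false(any(m$region_id == 2 & m$gene == "a"))  # [100,200) vs [200,300)
  expect_false("c" %in% m$gene)
  expect_equal(nrow(annotate_regions(reg[0, ], ann)), 0)
})

test_that("Welch concordance filter matches the closed-form statistic and is one-sided", {
  sc <- rbind(g = c(2.0, 2.1, 1.9, 0.0, 0.1, -0.1))
  colnames(sc) <- sprintf("P%d", 1:6)
  expr <- fake_expr(sc)
  res <- concordance_filter("g", expr, carriers = c("P1", "P2", "P3"),
                            neutral = c("P4", "P5", "P6"), direction = "gain")
  # equal variances 0.01: t = 2 / sqrt(2 * 0.01 / 3), Welch-Satterthwaite df = 4
  expect_equal(res$t_statistic, 2 / sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_true(res$kept)

  # identical groups: one-sided p = 0.5, dropped
  sc2 <- rbind(g = c(1, 2, 3, 1, 2, 3)); colnames(sc2) <- colnames(sc)
  res2 <- concordance_filter("g", fake_expr(sc2), c("P1", "P2", "P3"),
                             c("P4", "P5", "P6"), "gain")
  expect_equal(res2$p_one_sided, 0.5)
  expect_false(res2$kept)

  # carriers lower than neutral under a gain alternative: wrong direction
  res3 <- concordance_filter("g", expr, carriers = c("P4", "P5", "P6"),
                             neutral = c("P1", "P2", "P3"), direction = "gain")
  expect_gt(res3$p_one_sided, 0.5)
  expect_false(res3$kept)

  # anti-symmetry: same data under the loss alternative flips kept at the same |t|
  res4 <- concordance_filter("g", expr, carriers = c("P4", "P5", "P6"),
                             neutral = c("P1", "P2", "P3"), direction = "loss")
  expect_equal(abs(res4$t_statistic), abs(res3$t_statistic))
  expect_equal(res4$p_one_sided + res3$p_one_sided, 1, tolerance = 1e-12)
  expect_true(res4$kept)

  # undersized group: undetermined, not kept and not rejected
  res5 <- concordance_filter("g", expr, carriers = "P1",
                             neutral = c("P4", "P5", "P6"), direction = "gain")
  expect_true(is.na(res5$kept))
})

test_that("patient AGS takes the rank-extreme tails with deterministic tie-breaks", {
  # toy: 6 genes x 3 patients with hand-enumerable ranks, top_n = 1
  sc <- matrix(c( 2, -1, -1,    # gA: A is max
                 -2,  1,  1,    # gB: A is min
                  0,  3, -3,    # gC: B max, C min
                  0, -3,  3,    # gD: B min, C max
                  1,  0, -1,    # gE
                 -1,  0,  1),   # gF
               nrow = 6, byrow = TRUE,
               dimnames = list(c("gA", "gB", "gC", "gD", "gE", "gF"),
                               c("A", "B", "C")))
  expr <- fake_expr(sc)
  agsA <- build_patient_ags(expr, "A", top_n = 1)
  # A holds rank 3 for gA and gE; tie broken by scaled magnitude -> gA
  expect_equal(agsA$gene[agsA$direction == "up"], "gA")
  expect_equal(agsA$gene[agsA$direction == "down"], "gB")
  agsB <- build_patient_ags(expr, "B", top_n = 1)
  expect_equal(agsB$gene[agsB$direction == "up"], "gC")
  expect_equal(agsB$gene[agsB$direction == "down"], "gD")

  # up and down sets are disjoint and sizes are exactly 2 * top_n
  set.seed(11)
  big <- matrix(rnorm(400 * 5), 400, 5,
                dimnames = list(sprintf("g%03d", 1:400), sprintf("P%d", 1:5)))
  ags <- build_patient_ags(fake_expr(big), "P2", top_n = 100)
  expect_equal(nrow(ags), 200)
  expect_length(intersect(ags$gene[ags$direction == "up"],
                          ags$gene[ags$direction == "down"]), 0)
  expect_error(build_patient_ags(fake_expr(big), "P1", top_n = 300),
               "invalid-config")
})

test_that("common AGS applies the recurrence threshold and literature extension", {
  mk_ags <- function(p, genes) data.frame(gene = genes, direction = "up",
                                          patient = p, stringsAsFactors = FALSE)
  ags <- c(lapply(sprintf("P%d", 1:5), function(p) mk_ags(p, c("g1", "g2"))),
           list(mk_ags("P6", c("g2", "g3")), mk_ags("P7", "g3"),
                mk_ags("P8", "g3"), mk_ags("P9", "g3")))
  universe <- c("g1", "g2", "g3", "lit1")
  res <- suppressMessages(build_common_ags(ags, min_recurrence = 5,
                                           literature_genes = c("lit1", "lit2"),
                                           universe = universe))
  expect_setequal(res$gene, c("g1", "g2", "lit1"))      # g3 only in 4 patients
  expect_equal(res$provenance[res$gene == "lit1"], "literature")
  expect_equal(res$n_patients[res$gene == "g2"], 6)
  # lit2 is outside the universe and dropped
  expect_false("lit2" %in% res$gene)
  expect_warning(build_common_ags(ags, 5, character(), universe),
                 "literature")
})

test_that("direction-pure FGS reduction drops genes from mixed regions", {
  regions <- list(
    regions = data.frame(region_id = 1:2, chrom = "chr1",
                         start = c(0, 5000), end = c(1000, 6000)),
    carriers = data.frame(region_id = c(1, 1, 1, 2, 2),
                          patient = sprintf("P%d", 1:5),
                          direction = c("gain", "gain", "loss", "gain", "gain")))
  fgs <- structure(list(
    genes = c("a", "b"),
    annotation = data.frame(region_id = c(1, 2), gene = c("a", "b")),
    alterations = NULL, tests = NULL, regions = regions), class = "fgs")
  red <- build_common_fgs(fgs)
  expect_equal(red$gene, "b")           # region 1 mixes gains and losses
  expect_equal(red$direction, "gain")

  # all regions pure: reduction keeps everything
  regions$carriers$direction <- "gain"
  fgs$regions <- regions
  expect_setequal(build_common_fgs(fgs)$gene, c("a", "b"))
})

test_that("FGS recovers cis-responsive planted drivers inside recurrent regions", {
  co <- generate_cohort(small_config(seed = 13))
  cnas <- segment_cohort(co$probe_map, co$log_ratios)
  reg <- detect_recurrent_regions(cnas, 24, co$probe_map)
  expr <- preprocess_expression(co$expression)
  fgs <- build_fgs(reg, co$gene_annotation, expr, cnas)
  expect_true(all(co$truth$planted_drivers %in% fgs$genes))
  expect_true(all(fgs$genes %in% fgs$annotation$gene))   # FGS within annotated genes
})
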