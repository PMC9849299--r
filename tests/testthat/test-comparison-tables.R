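# Group-comparison rows, publication rendering with ULQ/NQ sentinels,
# matrix serialization round-trip, purity assessment, and the cross-model
# twofold classification.

test_that("summary-statistic rows reproduce published ratio and p columns", {
  ms <- publishedSummaries("microvessel")
  rows <- summarizeFromStats(ms[ms$model == "mouse", ], "WT", "5xFAD")
  get <- function(p, col) rows[rows$protein == p, col]
  expect_equal(signif(get("ASCT1", "ratio"), 2), 2.1)
  expect_equal(signif(get("LAT1", "ratio"), 2), 0.38)
  expect_equal(signif(get("4F2hc", "ratio"), 2), 1.4)
  expect_equal(signif(get("Abcb1", "ratio"), 2), 0.71)
  expect_lt(abs(get("LAT1", "p_value") - 0.008), 0.01)
  # ULQ in both groups: sentinels, no ratio, no p
  expect_true(is.na(get("OCT1", "ratio")))
  expect_true(is.na(get("OCT1", "p_value")))
  fmt <- formatComparisonTable(rows)
  expect_equal(fmt$control[fmt$protein == "OCT1"], "<0.15 (ULQ)")
  expect_equal(fmt$p_value[fmt$protein == "OCT1"], "")
})

test_that("noiseless synthetic matrices summarize to the generating means", {
  cfg <- simConfig(seed = 21, noiseCv = 0, biologicalCv = 0)
  sim <- simulateMrmDataset(cfg)
  q <- quantifyTransitions(sim$transitions, sim$spikeLoad)
  qe <- buildExpressionMatrix(q, sim$design)
  rows <- summarizeGroups(qe, "WT", "5xFAD", routQ = NA)
  quantRows <- rows[rows$control_status == "quantified", ]
  expect_equal(quantRows$control_mean,
               unname(cfg@abundances[quantRows$protein, "WT"]),
               tolerance = 1e-12)
  expect_equal(quantRows$ratio,
               unname(cfg@abundances[quantRows$protein, "5xFAD"] /
                        cfg@abundances[quantRows$protein, "WT"]),
               tolerance = 1e-12)
  expect_equal(signif(quantRows$ratio[quantRows$protein == "ASCT1"], 2), 2.1)
  # mixed rows: ULQ cells excluded from the group mean
  st <- exprStatus(qe); ex <- exprValues(qe)
  for (p in rownames(qe)[rowSums(st == "quantified") > 0]) {
    keep <- st[p, ] == "quantified" & sampleGroups(qe) == "WT"
    expect_equal(rows$control_mean[rows$protein == p],
                 mean(ex[p, keep]), tolerance = 1e-12)
  }
})

test_that("summarizing needs two groups and known labels", {
  cfg <- simConfig(seed = 22, groups = data.frame(label = "WT", n = 4L))
  sim <- simulateMrmDataset(cfg)
  q <- quantifyTransitions(sim$transitions, sim$spikeLoad)
  qe <- buildExpressionMatrix(q, sim$design)
  expect_error(summarizeGroups(qe, "WT", "WT"), "2 groups",
               class = "qtap_config_error")
  cfg2 <- simConfig(seed = 23)
  sim2 <- simulateMrmDataset(cfg2)
  qe2 <- buildExpressionMatrix(quantifyTransitions(sim2$transitions,
                                                   sim2$spikeLoad),
                               sim2$design)
  expect_error(summarizeGroups(qe2, "WT", "nonesuch"), "unknown group",
               class = "qtap_config_error")
})

test_that("expression matrices round-trip through the sentinel CSV format", {
  cfg <- simConfig(seed = 24)
  sim <- simulateMrmDataset(cfg)
  q <- quantifyTransitions(sim$transitions, sim$spikeLoad,
                           lloqTable = data.frame(protein = "CAT-1",
                                                  lloq = 0.15))
  qe <- buildExpressionMatrix(q, sim$design)
  path <- withr::local_tempfile(fileext = ".csv")
  writeExpressionMatrix(qe, path)
  back <- readExpressionMatrix(path)
  expect_identical(exprStatus(back), exprStatus(qe))
  expect_identical(sampleGroups(back), sampleGroups(qe))
  expect_equal(exprValues(back), exprValues(qe), tolerance = 1e-12)
  expect_equal(lloqBounds(back)["CAT-1", ], lloqBounds(qe)["CAT-1", ],
               tolerance = 1e-12)
})

test_that("purity assessment reports enrichment bounds and group equivalence", {
  mkExp <- function(vals, status, lloq, groups) {
    QtapExperiment(expression = vals, status = status, lloq = lloq,
                   group = groups)
  }
  samples <- sprintf("s%d", 1:4)
  mv <- matrix(c(2.9, 2.9, 2.9, 2.9, 29, 29, 29, 29), 2, 4, byrow = TRUE,
               dimnames = list(c("gGtp", "NaKATPase"), samples))
  mvSt <- matrix("quantified", 2, 4, dimnames = dimnames(mv))
  ti <- matrix(c(NA, NA, NA, NA, 70, 70, 70, 70), 2, 4, byrow = TRUE,
               dimnames = dimnames(mv))
  tiSt <- matrix(rep(c("ULQ", "quantified"), 4), 2, 4,
                 dimnames = dimnames(mv))
  tiLq <- matrix(c(0.03, NA), 2, 4, dimnames = dimnames(mv))
  grp <- c("WT", "WT", "AD", "AD")
  pa <- purityAssessment(mkExp(mv, mvSt, NULL, grp),
                         mkExp(ti, tiSt, tiLq, grp))
  expect_true(pa$enrichment$isLowerBound)
  expect_equal(pa$enrichment$ratio, 2.9 / 0.03, tolerance = 1e-12)
  # identical marker levels in both groups -> between-group p = 1
  expect_equal(unname(pa$betweenGroupP["gGtp"]), 1)
  expect_error(
    purityAssessment(mkExp(mv, mvSt, NULL, grp),
                     mkExp(ti[1, , drop = FALSE], tiSt[1, , drop = FALSE],
                           tiLq[1, , drop = FALSE], grp)),
    "marker absent", class = "qtap_config_error")
})

test_that("cross-model twofold flags reproduce the FATP1 pattern", {
  ms <- publishedSummaries("microvessel")
  mouse <- summarizeFromStats(ms[ms$model == "mouse", ], "WT", "5xFAD")
  rat <- summarizeFromStats(ms[ms$model == "rat", ], "WT", "TgF344-AD")
  fl <- crossModelFlags(mouse, rat, threshold = 2)
  fatp1 <- fl[fl$protein == "FATP1", ]
  expect_gt(fatp1$ratio_disease, 2)        # >2-fold higher in the rat model
  expect_lt(fatp1$ratio_wildtype, 0.5)     # >2-fold lower in WT rats
  expect_true(fatp1$flagged_disease && fatp1$flagged_wildtype)
  expect_equal(fatp1$classification, "model-specific")
  # ULQ on either side blocks the comparison
  expect_equal(fl$classification[fl$protein == "LAT1"], "not-comparable")
  expect_equal(fl$classification[fl$protein == "OCT1"], "not-comparable")
})

test_that("alteration classification follows the threshold rules and is swap-invariant", {
  expect_equal(classifyAlteration(2.8, 2.7), "interspecies")
  expect_equal(classifyAlteration(2.8, 2.7, ageComparison = TRUE),
               "age-dependent")
  expect_equal(classifyAlteration(4.3, 1 / 2.5), "model-specific")
  expect_equal(classifyAlteration(2.5, 1.2), "model-specific")
  expect_equal(classifyAlteration(1.1, 1.0), "none")
  expect_equal(classifyAlteration(NA, 1.0), "not-comparable")
  set.seed(606)
  rd <- exp(runif(50, -2, 2)); rw <- exp(runif(50, -2, 2))
  for (i in seq_along(rd))
    expect_identical(classifyAlteration(rd[i], rw[i]),
                     classifyAlteration(1 / rd[i], 1 / rw[i]))
  emptyA <- data.frame(protein = "X", control_status = "quantified",
                       treatment_status = "quantified", control_mean = 1,
                       treatment_mean = 1)
  emptyB <- data.frame(protein = "Y", control_status = "quantified",
                       treatment_status = "quantified", control_mean = 1,
                       treatment_mean = 1)
  expect_warning(fl0 <- crossModelFlags(emptyA, emptyB),
                 class = "qtap_warning")
  expect_equal(nrow(fl0), 0L)
})
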