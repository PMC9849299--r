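# Synthetic-data generators: config validation, determinism, noiseless
# identities, dropout behaviour, and Monte-Carlo effect recovery.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simConfig(transitionFractions = c(0.5, 0.3, 0.3, 0.1)),
               "transitionFractions", class = "qtap_config_error")
  expect_error(simConfig(groups = data.frame(label = "WT", n = 1L)),
               "groups", class = "qtap_config_error")
  expect_error(simConfig(spikeFmol = 0), "spikeFmol",
               class = "qtap_config_error")
  expect_error(simConfig(noiseCv = -0.1), "noiseCv",
               class = "qtap_config_error")
  expect_error(simConfig(primerEfficiency = 2.5), "primerEfficiency",
               class = "qtap_config_error")
  expect_error(simConfig(primerEfficiency = 1), "primerEfficiency",
               class = "qtap_config_error")
})

test_that("identical seed and config yield identical datasets", {
  cfg <- simConfig(seed = 99L)
  a <- simulateMrmDataset(cfg)
  b <- simulateMrmDataset(cfg)
  expect_identical(a, b)
  expect_identical(simulateAminoAcidDataset(cfg), simulateAminoAcidDataset(cfg))
  expect_identical(simulateQpcrDataset(cfg), simulateQpcrDataset(cfg))
  # a different seed changes the areas
  c2 <- simulateMrmDataset(simConfig(seed = 100L))
  expect_false(identical(a$transitions$peak_area, c2$transitions$peak_area))
})

test_that("noiseless areas satisfy the isotope-dilution identity exactly", {
  cfg <- oneProteinConfig(seed = 1, wt = 0.71, ad = 1.5,
                          noiseCv = 0, biologicalCv = 0)
  sim <- simulateMrmDataset(cfg)
  tr <- sim$transitions
  wide <- merge(tr[tr$label == "light", ],
                tr[tr$label == "heavy", c("sample_id", "transition_id",
                                          "peak_area")],
                by = c("sample_id", "transition_id"),
                suffixes = c("_l", "_h"))
  truth <- sim$truth$true_abundance[match(wide$sample_id,
                                          sim$truth$sample_id)]
  expect_equal(wide$peak_area_l / wide$peak_area_h,
               truth * cfg@proteinLoadUg / cfg@spikeFmol, tolerance = 1e-12)
  # generating means are the configured group means
  expect_equal(unique(sim$truth$true_abundance[sim$truth$group == "WT"]), 0.71)
  expect_equal(unique(sim$truth$true_abundance[sim$truth$group == "AD"]), 1.5)
})

test_that("zero true abundance leaves all light transitions undetected", {
  cfg <- oneProteinConfig(seed = 2, wt = 0, ad = 0, noiseCv = 0,
                          biologicalCv = 0)
  tr <- simulateMrmDataset(cfg)$transitions
  expect_false(any(tr$detected[tr$label == "light"]))
  expect_true(all(tr$detected[tr$label == "heavy"]))
})

test_that("at zero noise, lowering abundance never increases detected light transitions", {
  detectedCount <- function(a) {
    cfg <- oneProteinConfig(seed = 3, wt = a, ad = a, n = 2L,
                            noiseCv = 0, biologicalCv = 0)
    tr <- simulateMrmDataset(cfg)$transitions
    sum(tr$detected[tr$label == "light" & tr$sample_id == "WT_01"])
  }
  counts <- vapply(c(1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001, 0), detectedCount, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("amino-acid generator centres groups at the configured percent effects", {
  # noiseless: treatment/control ratio equals the configured effect exactly
  cfg <- simConfig(seed = 4, noiseCv = 0, aaEffects = c(histidine = 30))
  aa <- simulateAminoAcidDataset(cfg)
  lv <- relativeQuantify(aa$measurements, "WT")
  ctrl <- lv$level[lv$group == "WT"]
  trt <- lv$level[lv$group == "5xFAD"]
  expect_equal(mean(trt) / mean(ctrl), 1.30, tolerance = 1e-12)
  # effect 0 + noise 0: all samples identical
  cfg0 <- simConfig(seed = 5, noiseCv = 0, aaEffects = c(serine = 0))
  m0 <- simulateAminoAcidDataset(cfg0)$measurements
  expect_equal(length(unique(m0$analyte_area)), 1L)
})

test_that("amino-acid Monte-Carlo recovery: +39% alanine, n=9/9, CV 0.15", {
  grp <- data.frame(label = c("WT", "5xFAD"), n = c(9L, 9L))
  rec <- vapply(seq_len(500), function(i) {
    cfg <- simConfig(seed = 10000L + i, groups = grp, noiseCv = 0.15,
                     aaEffects = c(alanine = 39))
    aa <- simulateAminoAcidDataset(cfg)
    lv <- relativeQuantify(aa$measurements, "WT")
    compareAminoAcids(lv, "WT", "5xFAD")$percent_of_control
  }, 1)
  expect_lt(abs(mean(rec) - 139), 2)
})

test_that("qPCR generator: noiseless identities and Monte-Carlo fold recovery", {
  # true fold 2 with efficiency 2: target Ct exactly 1 cycle lower
  cfg <- simConfig(seed = 6, qpcrEffects = c(Gfap = 2), ctNoiseSd = 0)
  ct <- simulateQpcrDataset(cfg, sampleOffsetSd = 0)$ct
  gf <- ct[ct$gene == "Gfap", ]
  expect_equal(mean(gf$ct[gf$group == "WT"]) - mean(gf$ct[gf$group == "5xFAD"]),
               1, tolerance = 1e-12)
  # true fold 1 everywhere: ddCt recovery of exactly 1
  cfg1 <- simConfig(seed = 7, qpcrEffects = c(Gfap = 1, Aif1 = 1), ctNoiseSd = 0)
  fe <- normalizedFoldExpression(simulateQpcrDataset(cfg1)$ct, "WT")
  expect_equal(fe$fold, rep(1, nrow(fe)), tolerance = 1e-12)
  # fold 3.5, noise 0.2, n=7/6: mean recovered fold within 5% over 200 reps
  grp <- data.frame(label = c("WT", "5xFAD"), n = c(6L, 7L))
  rec <- vapply(seq_len(200), function(i) {
    cfg <- simConfig(seed = 20000L + i, groups = grp,
                     qpcrEffects = c(Gfap = 3.5), ctNoiseSd = 0.2)
    fe <- normalizedFoldExpression(simulateQpcrDataset(cfg)$ct, "WT")
    compareFoldExpression(fe, "WT", "5xFAD")
    mean(fe$fold[fe$gene == "Gfap" & fe$group == "5xFAD"])
  }, 1)
  expect_lt(abs(mean(rec) / 3.5 - 1), 0.05)
})
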