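# Transition pairing, the averaging/ULQ quantification rules, LLOQ from a
# dilution series, matrix assembly, and the scale/unit invariants.

test_that("light and heavy records pair per (sample, peptide, transition)", {
  r <- makeRecords(c(0.5, 0.6, 0.7, 0.8))
  pr <- pairTransitions(r)
  expect_equal(nrow(pr$pairs), 4L)
  expect_equal(nrow(pr$unpaired), 0L)

  # light row without a heavy partner is reported, not dropped silently
  r2 <- r[!(r$transition_id == "t4" & r$label == "heavy"), ]
  expect_warning(pr2 <- pairTransitions(r2), class = "qtap_warning")
  expect_equal(nrow(pr2$pairs), 3L)
  expect_equal(pr2$unpaired$transition_id, "t4")

  # 2 samples x 2 peptides x 3 transitions -> 12 pairs
  r3 <- do.call(rbind, lapply(c("s1", "s2"), function(s)
    rbind(makeRecords(c(1, 1, 1), sample = s),
          makeRecords(c(1, 1, 1), sample = s, protein = "P2",
                      peptide = "P2_pep"))))
  expect_equal(nrow(pairTransitions(r3)$pairs), 12L)

  # duplicated record is a data-integrity error listing the duplicate
  expect_error(pairTransitions(rbind(r, r[1, ])), "duplicate",
               class = "qtap_data_error")
})

test_that("peptide quantification averages 3-4 transition values, else ULQ", {
  # 3 transitions at ratio 0.5, spike 10 fmol, 50 ug -> 0.1 fmol/ug
  p <- pairTransitions(makeRecords(c(0.5, 0.5, 0.5)))$pairs
  q <- quantifyPeptide(p, spikeFmol = 10, proteinLoadUg = 50)
  expect_equal(q$expression, 0.1, tolerance = 1e-12)
  expect_equal(q$status, "quantified")

  # hand-computed mean: ratios 0.8/1.0/1.2/1.0, spike 5, 50 ug
  p4 <- pairTransitions(makeRecords(c(0.8, 1.0, 1.2, 1.0)))$pairs
  q4 <- quantifyPeptide(p4, spikeFmol = 5, proteinLoadUg = 50)
  expect_equal(sort(q4$transition_values[[1]]), c(0.08, 0.10, 0.10, 0.12),
               tolerance = 1e-12)
  expect_equal(q4$expression, mean(c(0.08, 0.10, 0.12, 0.10)),
               tolerance = 1e-12)

  # only 2 detected transitions -> ULQ, no expression, bound carried
  r <- makeRecords(c(0.5, 0.5, 0.5, 0.5))
  r$detected[r$label == "light" & r$transition_id %in% c("t3", "t4")] <- FALSE
  qu <- quantifyPeptide(pairTransitions(r)$pairs, 10, 50, lloq = 0.15)
  expect_equal(qu$status, "ULQ")
  expect_true(is.na(qu$expression))
  expect_equal(qu$lloq, 0.15)

  # detected pair with zero heavy area: internal standard missing
  bad <- pairTransitions(makeRecords(c(0.5, 0.5, 0.5)))$pairs
  bad$heavy_area[1] <- 0
  expect_error(quantifyPeptide(bad, 10, 50), "internal standard",
               class = "qtap_data_error")
})

test_that("LLOQ is the lowest dilution level yielding 3-4 transitions", {
  expect_equal(determineLloq(c(0.01, 0.03, 0.1), c(1L, 3L, 4L))$lloq, 0.03)
  r <- determineLloq(c(0.01, 0.03, 0.1), c(4L, 4L, 4L))
  expect_equal(r$lloq, 0.01)       # all qualify -> lowest level tested
  expect_warning(
    nm <- determineLloq(c(0.01, 0.03, 0.1), c(3L, 2L, 4L)),
    "non-monotone", class = "qtap_warning")
  expect_equal(nm$lloq, 0.01)
  none <- determineLloq(c(0.01, 0.03), c(1L, 2L))
  expect_false(none$quantifiable)
  expect_true(is.na(none$lloq))
})

test_that("expression matrix cells are exactly one of value/ULQ/NQ", {
  cfg <- oneProteinConfig(seed = 8, wt = 0.5, ad = 1.0, noiseCv = 0,
                          biologicalCv = 0)
  sim <- simulateMrmDataset(cfg)
  q <- quantifyTransitions(sim$transitions, sim$spikeLoad)
  qe <- buildExpressionMatrix(q, sim$design, panel = c("P1", "P2"))
  expect_s4_class(qe, "QtapExperiment")
  expect_true(all(exprStatus(qe)["P1", ] == "quantified"))
  expect_true(all(exprStatus(qe)["P2", ] == "NQ"))   # not in this dataset

  # two peptides mapped to one protein is a configuration error
  q2 <- q
  q2$peptide[1] <- "other_pep"
  expect_error(buildExpressionMatrix(q2, sim$design), "1:1",
               class = "qtap_config_error")
})

test_that("expression is scale-equivariant and inversely proportional to load", {
  r <- makeRecords(c(0.8, 1.0, 1.2, 1.0))
  base <- quantifyPeptide(pairTransitions(r)$pairs, 10, 50)$expression
  scaleBy <- function(rec, lab, c) {
    rec$peak_area[rec$label == lab] <- rec$peak_area[rec$label == lab] * c
    quantifyPeptide(pairTransitions(rec)$pairs, 10, 50)$expression
  }
  expect_equal(scaleBy(r, "light", 3), 3 * base, tolerance = 1e-12)
  expect_equal(scaleBy(r, "heavy", 3), base / 3, tolerance = 1e-12)
  doubled <- quantifyPeptide(pairTransitions(r)$pairs, 10, 100)$expression
  expect_equal(doubled, base / 2, tolerance = 1e-12)
})

test_that("noiseless end-to-end pipeline recovers ground truth to 1e-12", {
  cfg <- simConfig(seed = 9, noiseCv = 0, biologicalCv = 0)
  sim <- simulateMrmDataset(cfg)
  q <- quantifyTransitions(sim$transitions, sim$spikeLoad)
  qe <- buildExpressionMatrix(q, sim$design)
  ex <- exprValues(qe)
  tr <- sim$truth
  got <- ex[cbind(tr$protein, tr$sample_id)]
  quantified <- !is.na(got)
  expect_true(any(quantified))
  expect_equal(got[quantified], tr$true_abundance[quantified],
               tolerance = 1e-12)
  # the ULQ rows are exactly the sub-detection-floor proteins
  ulqProteins <- rownames(qe)[apply(exprStatus(qe) == "ULQ", 1, all)]
  expect_setequal(ulqProteins, c("CAT-1", "OCT1"))
})
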