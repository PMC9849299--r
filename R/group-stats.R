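## Statistical layer: pooled-variance unpaired t-tests (raw and
## summary-statistic forms), a robust FDR-controlled outlier screen,
## Shapiro-Wilk normality check, fold ratios, and exact noncentral-t
## power / sample-size calculations.

testResult <- function(t, df, p, outliers = character(), name) {
  structure(list(t_statistic = t, df = df, p_value = p,
                 outliers_removed = outliers, test_name = name),
            class = "qtap_test")
}

#' @export
print.qtap_test <- function(x, ...) {
  cat(x$test_name, "\n")
  if (is.na(x$t_statistic)) {
    cat("  not testable\n")
  } else {
    cat(sprintf("  t = %.4g, df = %g, p = %.4g\n",
                x$t_statistic, x$df, x$p_value))
  }
  if (length(x$outliers_removed))
    cat("  outliers removed:", paste(x$outliers_removed, collapse = ", "), "\n")
  invisible(x)
}

#' Unpaired pooled-variance Student's t-test on raw values
#'
#' Two-sided two-sample Student's t-test with pooled variance
#' `((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and `n1 + n2 - 2` degrees
#' of freedom. If either group has fewer than 2 usable values the result is
#' marked not testable (NA statistics) rather than raising an error, so that
#' entirely-ULQ groups render as blank p-values in reports.
#'
#' @param groupA,groupB numeric vectors of measurements (NAs dropped).
#' @param outliersRemoved character ids recorded in the result (bookkeeping
#'   for upstream outlier removal).
#' @return a `qtap_test` list: `t_statistic`, `df`, `p_value`,
#'   `outliers_removed`, `test_name`.
#' @export
studentTRaw <- function(groupA, groupB, outliersRemoved = character()) {
  a <- groupA[!is.na(groupA)]
  b <- groupB[!is.na(groupB)]
  name <- "unpaired two-sided Student's t-test (pooled variance)"
  if (length(a) < 2L || length(b) < 2L)
    return(testResult(NA_real_, NA_real_, NA_real_, outliersRemoved, name))
  res <- studentTSummary(mean(a), stats::sd(a), length(a),
                         mean(b), stats::sd(b), length(b))
  res$outliers_removed <- outliersRemoved
  res
}

#' Unpaired pooled-variance Student's t-test from summary statistics
#'
#' Identical formulas to [studentTRaw()] but starting from group means, SDs
#' and sizes, so p-values can be recomputed from published
#' mean +/- SD tables.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return a `qtap_test` list (see [studentTRaw()]).
#' @examples
#' # LAT1 microvessel summaries: p rounds to 0.008
#' studentTSummary(0.32, 0.14, 6, 0.12, 0.05, 6)$p_value
#' @export
studentTSummary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) stopConfig("group sizes must be >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  testResult(t, df, p, character(),
             "unpaired two-sided Student's t-test (pooled variance)")
}

#' Robust FDR-controlled outlier screen (ROUT-style)
#'
#' Univariate variant of robust-regression-plus-outlier removal: the robust
#' location is the median; the robust scale (RSDR) is the 68.27th percentile
#' of the absolute residuals with the small-sample correction `n / (n - 1)`;
#' candidate outliers are ranked by absolute residual and flagged by a
#' Benjamini-Hochberg-style step-down rule on two-sided t tail
#' probabilities (df = n - 2), controlling the false discovery rate at `q`.
#' At most 30 percent of the values can be flagged. `q = 0` flags nothing.
#'
#' @param values numeric vector, length >= 3.
#' @param q maximum desired FDR, in \[0, 0.1\]; default 0.01 (1 percent).
#' @return list with `kept` (values with outliers removed), `flagged`
#'   (indices into `values`), `rsdr`, and the per-candidate table
#'   `candidates`.
#' @export
routOutliers <- function(values, q = 0.01) {
  if (q < 0 || q > 0.1)
    stopConfig("q: maximum desired FDR must lie in [0, 0.1]")
  if (length(values) < 3L)
    stopConfig("outlier screen needs at least 3 values")
  n <- length(values)
  res <- values - stats::median(values)
  rsdr <- unname(stats::quantile(abs(res), 0.6827, type = 7)) * n / (n - 1)
  flagged <- integer()
  cand <- data.frame(index = integer(), abs_residual = numeric(),
                     p = numeric(), threshold = numeric())
  if (q > 0 && rsdr > 0) {
    ord <- order(abs(res), decreasing = TRUE)
    maxFlag <- floor(0.3 * n)
    if (maxFlag >= 1L) {
      idx <- ord[seq_len(maxFlag)]
      p <- 2 * stats::pt(-abs(res[idx]) / rsdr, df = n - 2)
      thr <- q * seq_len(maxFlag) / n
      cand <- data.frame(index = idx, abs_residual = abs(res[idx]),
                         p = p, threshold = thr)
      pass <- which(p < thr)
      if (length(pass)) flagged <- sort(idx[seq_len(max(pass))])
    }
  }
  list(kept = if (length(flagged)) values[-flagged] else values,
       flagged = flagged, rsdr = rsdr, candidates = cand)
}

#' Shapiro-Wilk normality check
#'
#' Tests the data against the null hypothesis of normality; "pass" means
#' the null is not rejected at `alpha`.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p`, `pass`; for constant (degenerate)
#'   input, `degenerate = TRUE` with NA statistics.
#' @export
normalityCheck <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stopConfig("normality check needs >= 3 values")
  if (stats::sd(values) == 0)
    return(list(statistic = NA_real_, p = NA_real_, pass = NA,
                degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       pass = sw$p.value >= alpha, degenerate = FALSE)
}

#' Fold ratio between group means
#'
#' `ratio = meanTreatment / meanControl`, full precision; rounding to the
#' 2-significant-figure table convention happens only at the report layer
#' ([formatComparisonTable()]).
#'
#' @param meanTreatment,meanControl group means; `meanControl` must be > 0
#'   for a defined ratio (otherwise NA is returned).
#' @return numeric ratio (NA when undefined).
#' @export
foldRatio <- function(meanTreatment, meanControl) {
  ifelse(is.na(meanControl) | meanControl <= 0, NA_real_,
         meanTreatment / meanControl)
}

#' Specification for a two-sample t-test power calculation
#'
#' @param delta mean difference in measurement units; `delta = 0` computes
#'   the test's size (power equals alpha) but is rejected by
#'   [minSampleSize()].
#' @param sd1,sd2 the two group SDs; pooled as `sqrt((sd1^2 + sd2^2)/2)`.
#' @param alpha two-sided significance level (default 0.05).
#' @param targetPower desired power (default 0.80).
#' @return classed list used by [powerTwoSampleT()] / [minSampleSize()].
#' @export
powerSpec <- function(delta, sd1, sd2, alpha = 0.05, targetPower = 0.80) {
  if (alpha <= 0 || alpha >= 1) stopConfig("alpha: must lie in (0, 1)")
  if (targetPower <= 0 || targetPower >= 1)
    stopConfig("targetPower: must lie in (0, 1)")
  if (sd1 < 0 || sd2 < 0) stopConfig("sd1/sd2: must be >= 0")
  structure(list(delta = delta, sd1 = sd1, sd2 = sd2, alpha = alpha,
                 targetPower = targetPower), class = "qtap_power_spec")
}

#' Exact power of the two-sided two-sample t-test
#'
#' Noncentral-t power with `df = 2n - 2` and noncentrality
#' `|delta| / (sdPooled * sqrt(2/n))`, `sdPooled = sqrt((sd1^2 + sd2^2)/2)`:
#' `power = P(|T'| > t_crit)`.
#'
#' @param nPerGroup observations per group (>= 2); may be a vector.
#' @param spec a [powerSpec()].
#' @return numeric power in (0, 1).
#' @export
powerTwoSampleT <- function(nPerGroup, spec) {
  stopifnot(inherits(spec, "qtap_power_spec"))
  if (any(nPerGroup < 2L)) stopConfig("nPerGroup: must be >= 2")
  sdPooled <- sqrt((spec$sd1^2 + spec$sd2^2) / 2)
  df <- 2 * nPerGroup - 2
  ncp <- abs(spec$delta) / (sdPooled * sqrt(2 / nPerGroup))
  tCrit <- stats::qt(1 - spec$alpha / 2, df)
  stats::pt(-tCrit, df, ncp) + 1 - stats::pt(tCrit, df, ncp)
}

#' Minimum per-group sample size for a target power
#'
#' Smallest integer `n >= 2` with `powerTwoSampleT(n, spec) >=
#' spec$targetPower`, found by incrementing n until satisfied.
#'
#' @param spec a [powerSpec()].
#' @return integer observations per group.
#' @examples
#' # rat Abcg2 microvessel summaries reproduce 6 observations per group
#' minSampleSize(powerSpec(delta = 0.37 - 0.12, sd1 = 0.040, sd2 = 0.18))
#' @export
minSampleSize <- function(spec) {
  stopifnot(inherits(spec, "qtap_power_spec"))
  if (spec$delta == 0)
    stopConfig("delta: must be non-zero for a sample-size search to terminate")
  n <- 2L
  while (powerTwoSampleT(n, spec) < spec$targetPower) n <- n + 1L
  n
}
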