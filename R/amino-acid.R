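## Isotope-dilution relative quantification of amino acids:
## analyte / internal-standard area ratios per normalizer unit,
## percent-of-control reporting and the method-acceptance precision gate.

#' Relative amino-acid quantification against internal standards
#'
#' Per measurement, `level = (analyte_area / is_area) / normalizer` (the
#' normalizer is sample volume in uL for plasma, tissue mass in mg for
#' brain). `percent_of_control` scales each level so that the designated
#' control group's mean is 100 for every analyte (and matrix).
#'
#' @param measurements data.frame with columns `sample_id`, `group`,
#'   `analyte`, `analyte_area`, `is_area`, `normalizer` (optionally
#'   `matrix`).
#' @param controlGroup label of the control group.
#' @return data.frame with `sample_id`, `group`, `analyte`, `level`,
#'   `percent_of_control`.
#' @export
relativeQuantify <- function(measurements, controlGroup) {
  need <- c("sample_id", "group", "analyte", "analyte_area", "is_area",
            "normalizer")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stopFormat("amino-acid table lacks required column(s): ",
               paste(miss, collapse = ", "))
  if (any(is.na(measurements$is_area) | measurements$is_area <= 0))
    stopData("missing or non-positive internal-standard area")
  if (any(measurements$normalizer <= 0))
    stopData("normalizer must be > 0")
  if (!controlGroup %in% measurements$group)
    stopConfig("unknown control group: ", controlGroup)
  m <- measurements
  m$level <- (m$analyte_area / m$is_area) / m$normalizer
  key <- if ("matrix" %in% names(m)) paste(m$analyte, m$matrix, sep = "\r")
         else m$analyte
  ctrlMean <- tapply(m$level[m$group == controlGroup],
                     key[m$group == controlGroup], mean)
  m$percent_of_control <- 100 * m$level / as.vector(ctrlMean[key])
  m[, c("sample_id", "group", "analyte", "level", "percent_of_control")]
}

#' Compare amino-acid levels between groups
#'
#' Unpaired pooled-variance Student's t-test on the relative levels per
#' analyte (delegated to [studentTRaw()], after the optional robust outlier
#' screen), plus the percent change of the treatment group. By default the
#' percent change is the ratio of group means
#' (`100 * meanTreatment / meanControl - 100`); `method = "mean_of_ratios"`
#' averages per-sample percent-of-control values instead.
#'
#' @param levels data.frame from [relativeQuantify()].
#' @param controlGroup,treatmentGroup group labels.
#' @param routQ FDR for [routOutliers()]; `NA` disables outlier removal
#'   (the default — the small per-analyte n makes screening optional).
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return data.frame per analyte: `percent_change`, `percent_of_control`,
#'   `t_statistic`, `p_value`, `outliers_removed`.
#' @export
compareAminoAcids <- function(levels, controlGroup, treatmentGroup,
                              routQ = NA,
                              method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  for (g in c(controlGroup, treatmentGroup))
    if (!g %in% levels$group) stopConfig("unknown group label: ", g)
  rows <- lapply(split(levels, levels$analyte), function(d) {
    a <- d$level[d$group == controlGroup]
    b <- d$level[d$group == treatmentGroup]
    names(a) <- d$sample_id[d$group == controlGroup]
    names(b) <- d$sample_id[d$group == treatmentGroup]
    if (length(a) < 2L || length(b) < 2L)
      stopData("analyte ", d$analyte[1], ": need >= 2 samples per group")
    removed <- character()
    if (!is.na(routQ)) {
      oa <- routOutliers(a, routQ); ob <- routOutliers(b, routQ)
      removed <- c(names(a)[oa$flagged], names(b)[ob$flagged])
      a <- oa$kept; b <- ob$kept
    }
    poc <- if (method == "ratio_of_means") 100 * mean(b) / mean(a)
           else mean(100 * b / mean(a))
    tt <- studentTRaw(a, b, outliersRemoved = removed)
    data.frame(analyte = d$analyte[1],
               control_n = length(a), treatment_n = length(b),
               percent_of_control = poc,
               percent_change = poc - 100,
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               outliers_removed = paste(removed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Method-acceptance precision gate
#'
#' Relative standard deviation of repeated QC measurements,
#' `RSD% = 100 * sd / mean`; the method passes when RSD <= 15 percent
#' (inclusive).
#'
#' @param qcReplicates numeric vector of >= 3 repeated measurements.
#' @param maxRsd acceptance threshold in percent (default 15).
#' @return list with `rsd` (percent), `pass`; `rsd = NA` and `pass = NA`
#'   when the mean is 0 (undefined RSD).
#' @export
precisionGate <- function(qcReplicates, maxRsd = 15) {
  if (length(qcReplicates) < 3L)
    stopConfig("precision gate needs >= 3 replicates")
  m <- mean(qcReplicates)
  if (m == 0) return(list(rsd = NA_real_, pass = NA))
  rsd <- 100 * stats::sd(qcReplicates) / m
  list(rsd = rsd, pass = rsd <= maxRsd)
}
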