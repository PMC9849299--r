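## qPCR fold expression: efficiency-corrected delta-delta-Ct with
## housekeeping normalization and calibrator-group scaling. With
## efficiency 2 this reduces exactly to the classic 2^-ddCt form.

#' Normalized fold gene expression from Ct values
#'
#' Per sample, `dCt = Ct_target - Ct_housekeeping`; per gene,
#' `ddCt = dCt - mean(dCt)` over the calibrator group; the fold is
#' `efficiency^(-ddCt)`. The calibrator group's geometric-mean fold is 1 by
#' construction. A global Ct shift applied to all genes of a sample (RNA
#' input differences) cancels in dCt.
#'
#' @param records data.frame with columns `sample_id`, `group`, `gene`,
#'   `ct`, `is_housekeeping`, and optionally `efficiency` (fold per cycle,
#'   in (1, 2]; default 2).
#' @param calibratorGroup label of the calibrator (control) group.
#' @return data.frame with `sample_id`, `group`, `gene`, `dct`, `ddct`,
#'   `fold`.
#' @export
normalizedFoldExpression <- function(records, calibratorGroup) {
  need <- c("sample_id", "group", "gene", "ct", "is_housekeeping")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopFormat("Ct table lacks required column(s): ",
               paste(miss, collapse = ", "))
  if (!"efficiency" %in% names(records)) records$efficiency <- 2
  if (any(records$efficiency <= 1 | records$efficiency > 2))
    stopConfig("efficiency: must lie in (1, 2]")
  if (any(records$ct <= 0)) stopData("ct values must be > 0")
  if (!calibratorGroup %in% records$group)
    stopConfig("unknown calibrator group: ", calibratorGroup)
  hk <- records[records$is_housekeeping, ]
  hkCt <- tapply(hk$ct, hk$sample_id, mean)
  noHk <- setdiff(unique(records$sample_id), names(hkCt))
  if (length(noHk))
    stopData("missing housekeeping Ct for sample(s): ",
             paste(noHk, collapse = ", "))
  d <- records
  d$dct <- d$ct - as.vector(hkCt[d$sample_id])
  calMean <- tapply(d$dct[d$group == calibratorGroup],
                    d$gene[d$group == calibratorGroup], mean)
  noCal <- setdiff(unique(d$gene), names(calMean))
  if (length(noCal))
    stopData("no calibrator-group observations for gene(s): ",
             paste(noCal, collapse = ", "))
  d$ddct <- d$dct - as.vector(calMean[d$gene])
  d$fold <- d$efficiency^(-d$ddct)
  d[, c("sample_id", "group", "gene", "dct", "ddct", "fold")]
}

#' Compare fold expression between groups
#'
#' Unpaired pooled-variance Student's t-test on the per-sample fold values
#' per gene (delegated to [studentTRaw()]); by default on the linear fold
#' scale (matching mean +/- SD bar displays), optionally on log folds.
#'
#' @param folds data.frame from [normalizedFoldExpression()].
#' @param controlGroup,treatmentGroup group labels.
#' @param scale `"linear"` (default) or `"log"`.
#' @return data.frame per gene: group means, `fold_ratio`, `t_statistic`,
#'   `p_value`.
#' @export
compareFoldExpression <- function(folds, controlGroup, treatmentGroup,
                                  scale = c("linear", "log")) {
  scale <- match.arg(scale)
  for (g in c(controlGroup, treatmentGroup))
    if (!g %in% folds$group) stopConfig("unknown group label: ", g)
  rows <- lapply(split(folds, folds$gene), function(d) {
    a <- d$fold[d$group == controlGroup]
    b <- d$fold[d$group == treatmentGroup]
    if (length(a) < 2L || length(b) < 2L)
      stopData("gene ", d$gene[1], ": need >= 2 samples per group")
    ta <- if (scale == "log") log(a) else a
    tb <- if (scale == "log") log(b) else b
    tt <- studentTRaw(ta, tb)
    data.frame(gene = d$gene[1],
               control_mean = mean(a), treatment_mean = mean(b),
               fold_ratio = mean(b) / mean(a),
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
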