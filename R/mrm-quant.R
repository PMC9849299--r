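## MRM quantification: paired light/heavy transition areas -> absolute
## protein expression (fmol/ug total protein), with the transition-averaging
## rule (mean of 3-4 per-transition values), the ULQ rule (<= 2 detected
## transitions) and the dilution-series LLOQ definition.

transitionCols <- c("sample_id", "protein", "peptide", "transition_id",
                    "label", "peak_area", "detected")

#' Pair light and heavy transition records
#'
#' Groups transition records into light/heavy pairs per
#' (sample, peptide, transition). Records without a partner in the other
#' isotope channel are not silently dropped: they are returned in an
#' `unpaired` report (with a warning).
#'
#' @param records data.frame of transition records with columns
#'   `sample_id`, `protein`, `peptide`, `transition_id`, `label`
#'   (`"light"`/`"heavy"`), `peak_area`, `detected`.
#' @return list with `pairs` (one row per matched transition, columns
#'   `light_area`, `heavy_area`, `light_detected`, `heavy_detected`) and
#'   `unpaired` (the partner-less records).
#' @export
pairTransitions <- function(records) {
  miss <- setdiff(transitionCols, names(records))
  if (length(miss))
    stopFormat("transition table lacks required column(s): ",
               paste(miss, collapse = ", "))
  if (any(records$peak_area < 0, na.rm = TRUE))
    stopData("peak_area must be >= 0")
  if (!all(records$label %in% c("light", "heavy")))
    stopData("label must be 'light' or 'heavy'")
  key <- paste(records$sample_id, records$peptide, records$transition_id,
               records$label, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("sample_id", "peptide", "transition_id",
                                      "label")]
    stopData("duplicate transition record(s): ",
             paste(apply(dup, 1, paste, collapse = "/"), collapse = "; "))
  }
  l <- records[records$label == "light", ]
  h <- records[records$label == "heavy", ]
  pairs <- merge(
    l[, c("sample_id", "protein", "peptide", "transition_id", "peak_area",
          "detected")],
    h[, c("sample_id", "peptide", "transition_id", "peak_area", "detected")],
    by = c("sample_id", "peptide", "transition_id"),
    suffixes = c("_light", "_heavy"))
  names(pairs)[names(pairs) == "peak_area_light"] <- "light_area"
  names(pairs)[names(pairs) == "peak_area_heavy"] <- "heavy_area"
  names(pairs)[names(pairs) == "detected_light"] <- "light_detected"
  names(pairs)[names(pairs) == "detected_heavy"] <- "heavy_detected"
  pkey <- paste(pairs$sample_id, pairs$peptide, pairs$transition_id, sep = "\r")
  lkey <- paste(l$sample_id, l$peptide, l$transition_id, sep = "\r")
  hkey <- paste(h$sample_id, h$peptide, h$transition_id, sep = "\r")
  unpaired <- rbind(l[!(lkey %in% pkey), ], h[!(hkey %in% pkey), ])
  rownames(unpaired) <- NULL
  if (nrow(unpaired))
    warnQtap(nrow(unpaired), " transition record(s) lack a light/heavy ",
             "partner and were excluded from quantification")
  ord <- order(pairs$sample_id, pairs$peptide, pairs$transition_id)
  pairs <- pairs[ord, ]
  rownames(pairs) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Quantify one peptide in one sample from its transition pairs
#'
#' Each transition pair in which both the light (endogenous) and heavy
#' (internal standard) channels are detected contributes a quantitative
#' value `(light_area / heavy_area) * spikeFmol / proteinLoadUg` in fmol/ug
#' total protein. When 3 or 4 values contribute, protein expression is their
#' arithmetic mean; with 2 or fewer the protein is reported under the limit
#' of quantification (ULQ), carrying the supplied `lloq` bound.
#'
#' @param pairs data.frame of transition pairs for a single
#'   (sample, peptide), as produced by [pairTransitions()].
#' @param spikeFmol labelled-peptide spike (fmol), > 0.
#' @param proteinLoadUg total protein load (ug), > 0.
#' @param lloq LLOQ bound (fmol/ug) attached when the result is ULQ.
#' @return one-row data.frame with `sample_id`, `protein`, `peptide`,
#'   `n_detected`, `status` (`"quantified"`/`"ULQ"`), `expression`
#'   (NA when ULQ), `lloq`, and a list column `transition_values`.
#' @export
quantifyPeptide <- function(pairs, spikeFmol, proteinLoadUg,
                            lloq = NA_real_) {
  if (spikeFmol <= 0) stopConfig("spikeFmol: must be > 0")
  if (proteinLoadUg <= 0) stopConfig("proteinLoadUg: must be > 0")
  if (length(unique(paste(pairs$sample_id, pairs$peptide))) != 1L)
    stopData("quantifyPeptide expects pairs for exactly one (sample, peptide)")
  contrib <- pairs$light_detected & pairs$heavy_detected
  if (any(contrib & pairs$heavy_area == 0))
    stopData("internal standard missing: detected pair with zero heavy area ",
             "for peptide ", pairs$peptide[1], " in sample ",
             pairs$sample_id[1])
  vals <- (pairs$light_area[contrib] / pairs$heavy_area[contrib]) *
    spikeFmol / proteinLoadUg
  nDet <- sum(contrib)
  quantified <- nDet >= 3L
  data.frame(
    sample_id = pairs$sample_id[1],
    protein = pairs$protein[1],
    peptide = pairs$peptide[1],
    n_detected = nDet,
    status = if (quantified) "quantified" else "ULQ",
    expression = if (quantified) mean(vals) else NA_real_,
    lloq = lloq,
    transition_values = I(list(vals)),
    stringsAsFactors = FALSE)
}

#' Quantify every (sample, peptide) in a transition table
#'
#' Convenience wrapper: pairs the records once, then applies
#' [quantifyPeptide()] per sample and peptide with each sample's spike and
#' load.
#'
#' @param transitions transition record table (see [pairTransitions()]).
#' @param spikeLoad data.frame with `sample_id`, `spike_fmol`,
#'   `protein_load_ug`.
#' @param lloqTable optional data.frame with `protein`, `lloq` giving the
#'   per-protein LLOQ bound (fmol/ug) attached to ULQ results.
#' @return data.frame of peptide quantifications, one row per
#'   (sample, peptide).
#' @export
quantifyTransitions <- function(transitions, spikeLoad, lloqTable = NULL) {
  miss <- setdiff(c("sample_id", "spike_fmol", "protein_load_ug"),
                  names(spikeLoad))
  if (length(miss))
    stopFormat("spike/load table lacks required column(s): ",
               paste(miss, collapse = ", "))
  pr <- pairTransitions(transitions)
  pairs <- pr$pairs
  unknown <- setdiff(unique(pairs$sample_id), spikeLoad$sample_id)
  if (length(unknown))
    stopConfig("no spike/load entry for sample(s): ",
               paste(unknown, collapse = ", "))
  sl <- spikeLoad[match(pairs$sample_id, spikeLoad$sample_id), ]
  out <- lapply(split(seq_len(nrow(pairs)),
                      paste(pairs$sample_id, pairs$peptide, sep = "\r")),
                function(i) {
    bound <- NA_real_
    if (!is.null(lloqTable)) {
      j <- match(pairs$protein[i[1]], lloqTable$protein)
      if (!is.na(j)) bound <- lloqTable$lloq[j]
    }
    quantifyPeptide(pairs[i, ], sl$spike_fmol[i[1]], sl$protein_load_ug[i[1]],
                    lloq = bound)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Determine the lower limit of quantification from a dilution series
#'
#' The LLOQ is the lowest labelled-peptide level at which the peptide
#' produces signal peaks with 3 or 4 transitions. If a qualifying level lies
#' below a failing one (non-monotone series) a warning is raised and the
#' lowest qualifying level is still returned; if no level qualifies the
#' protein is reported not quantifiable.
#'
#' @param levels numeric vector of labelled-peptide concentrations (any
#'   consistent unit, e.g. fmol/ug), at least 2 distinct levels.
#' @param nDetected integer vector of detected-transition counts per level.
#' @return list with `lloq` (NA when not quantifiable), `quantifiable`
#'   logical, and the qualifying rule used.
#' @export
determineLloq <- function(levels, nDetected) {
  if (length(levels) != length(nDetected))
    stopData("levels and nDetected must have equal length")
  if (length(unique(levels)) < 2L)
    stopData("dilution series needs at least 2 distinct levels")
  ord <- order(levels)
  levels <- levels[ord]
  nDetected <- nDetected[ord]
  ok <- nDetected >= 3L & nDetected <= 4L
  if (!any(ok))
    return(list(lloq = NA_real_, quantifiable = FALSE,
                rule = "lowest level with 3-4 detected transitions"))
  lloq <- levels[which(ok)[1]]
  if (any(!ok & levels > lloq))
    warnQtap("non-monotone dilution series: level(s) above the LLOQ failed ",
             "the 3-transition rule; returning lowest qualifying level")
  list(lloq = lloq, quantifiable = TRUE,
       rule = "lowest level with 3-4 detected transitions")
}

#' Assemble an absolute expression matrix from peptide quantifications
#'
#' Builds the proteins x samples [QtapExperiment-class] grid. Every cell is
#' exactly one of: a quantified value (fmol/ug), ULQ with its LLOQ bound, or
#' NQ (protein not measured in that dataset). The peptide-to-protein map
#' must be 1:1 (single surrogate peptide per protein).
#'
#' @param quants data.frame from [quantifyTransitions()] (or rbind-ed
#'   [quantifyPeptide()] rows).
#' @param design data.frame with `sample_id`, `group`.
#' @param panel optional character vector of proteins the matrix should
#'   cover; proteins without any quantification are reported NQ.
#' @param gene optional named character vector mapping protein to gene
#'   symbol for `rowData`.
#' @return a [QtapExperiment-class].
#' @export
buildExpressionMatrix <- function(quants, design, panel = NULL, gene = NULL) {
  map <- unique(quants[, c("protein", "peptide")])
  bad <- map$protein[duplicated(map$protein)]
  if (length(bad))
    stopConfig("peptide-to-protein map must be 1:1; multiple peptides for: ",
               paste(unique(bad), collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(design)))
    stopFormat("design table lacks required column(s): sample_id, group")
  samples <- design$sample_id
  proteins <- if (is.null(panel)) unique(quants$protein) else panel
  dn <- list(proteins, samples)
  ex <- matrix(NA_real_, length(proteins), length(samples), dimnames = dn)
  st <- matrix("NQ", length(proteins), length(samples), dimnames = dn)
  lq <- matrix(NA_real_, length(proteins), length(samples), dimnames = dn)
  keep <- quants$protein %in% proteins & quants$sample_id %in% samples
  q <- quants[keep, ]
  idx <- cbind(match(q$protein, proteins), match(q$sample_id, samples))
  st[idx] <- q$status
  ex[idx] <- ifelse(q$status == "quantified", q$expression, NA_real_)
  lq[idx] <- ifelse(q$status == "ULQ", q$lloq, NA_real_)
  QtapExperiment(expression = ex, status = st, lloq = lq,
                 group = design$group[match(samples, design$sample_id)],
                 gene = if (is.null(gene)) NULL else unname(gene[proteins]))
}
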