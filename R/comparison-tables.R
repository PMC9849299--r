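## Reporting surfaces: publication-shaped group-comparison tables with
## ULQ/NQ sentinels, expression-matrix serialization with round-trip
## fidelity, microvessel purity assessment, and cross-model twofold
## comparison with interspecies / model-specific classification.

groupCellSummary <- function(vals, stats, bounds, minQuantified = 2L) {
  quant <- stats == "quantified"
  if (sum(quant) >= minQuantified) {
    list(status = "quantified", values = vals[quant], lloq = NA_real_)
  } else if (any(stats == "ULQ")) {
    b <- bounds[stats == "ULQ"]
    list(status = "ULQ", values = numeric(),
         lloq = if (all(is.na(b))) NA_real_ else max(b, na.rm = TRUE))
  } else {
    list(status = "NQ", values = numeric(), lloq = NA_real_)
  }
}

#' Summarize an expression matrix into group-comparison rows
#'
#' Per protein: mean +/- SD per group (ULQ/NQ cells excluded), the
#' treatment/control fold ratio, and a pooled-variance unpaired t-test run
#' after the robust outlier screen ([routOutliers()]). A group with fewer
#' than `minQuantified` quantified cells is reported ULQ (with its bound) or
#' NQ, and the ratio and p-value are withheld for such rows.
#'
#' @param x a [QtapExperiment-class] with at least two groups.
#' @param control,treatment group labels; the ratio is treatment / control.
#' @param routQ FDR for the outlier screen; `NA` disables outlier removal.
#' @param minQuantified minimum quantified cells for a group summary.
#' @return data.frame with one row per protein: per-group n/mean/sd/status/
#'   lloq, `ratio`, `t_statistic`, `p_value`, `outliers_removed`
#'   (comma-separated sample ids).
#' @export
summarizeGroups <- function(x, control, treatment, routQ = 0.01,
                            minQuantified = 2L) {
  stopifnot(is(x, "QtapExperiment"))
  grp <- sampleGroups(x)
  if (length(unique(grp)) < 2L)
    stopConfig("expression matrix must contain at least 2 groups")
  for (g in c(control, treatment))
    if (!g %in% grp) stopConfig("unknown group label: ", g)
  ex <- exprValues(x); st <- exprStatus(x); lq <- lloqBounds(x)
  gene <- if ("gene" %in% names(rowData(x))) rowData(x)$gene
          else rep(NA_character_, nrow(x))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    cells <- lapply(c(control, treatment), function(g) {
      j <- which(grp == g)
      groupCellSummary(ex[i, j], st[i, j], lq[i, j], minQuantified)
    })
    names(cells) <- c("control", "treatment")
    out <- data.frame(
      protein = rownames(x)[i], gene = gene[i],
      control_status = cells$control$status,
      control_n = length(cells$control$values),
      control_mean = NA_real_, control_sd = NA_real_,
      control_lloq = cells$control$lloq,
      treatment_status = cells$treatment$status,
      treatment_n = length(cells$treatment$values),
      treatment_mean = NA_real_, treatment_sd = NA_real_,
      treatment_lloq = cells$treatment$lloq,
      ratio = NA_real_, t_statistic = NA_real_, p_value = NA_real_,
      outliers_removed = "", stringsAsFactors = FALSE)
    if (cells$control$status == "quantified" &&
        cells$treatment$status == "quantified") {
      keepC <- cells$control$values; keepT <- cells$treatment$values
      removed <- character()
      if (!is.na(routQ)) {
        oc <- routOutliers(keepC, routQ); ot <- routOutliers(keepT, routQ)
        removed <- c(names(cells$control$values)[oc$flagged],
                     names(cells$treatment$values)[ot$flagged])
        keepC <- oc$kept; keepT <- ot$kept
      }
      out$control_n <- length(keepC)
      out$control_mean <- mean(keepC); out$control_sd <- stats::sd(keepC)
      out$treatment_n <- length(keepT)
      out$treatment_mean <- mean(keepT); out$treatment_sd <- stats::sd(keepT)
      out$ratio <- foldRatio(out$treatment_mean, out$control_mean)
      tt <- studentTRaw(keepC, keepT, outliersRemoved = removed)
      out$t_statistic <- tt$t_statistic
      out$p_value <- tt$p_value
      out$outliers_removed <- paste(removed, collapse = ",")
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Build comparison rows from published summary statistics
#'
#' Accepts a long table of per-group summaries (as printed in mean +/- SD
#' comparison tables) and produces the same row layout as
#' [summarizeGroups()], with p-values from [studentTSummary()]. ULQ rows
#' carry their printed bound and get no ratio or p-value.
#'
#' @param stats data.frame with columns `protein`, `group`, `mean`, `sd`,
#'   `n`, `status` (`"quantified"`/`"ULQ"`/`"NQ"`), `lloq`; optionally
#'   `gene`.
#' @param control,treatment group labels.
#' @return data.frame as in [summarizeGroups()].
#' @export
summarizeFromStats <- function(stats, control, treatment) {
  need <- c("protein", "group", "mean", "sd", "n", "status", "lloq")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stopFormat("summary table lacks required column(s): ",
               paste(miss, collapse = ", "))
  for (g in c(control, treatment))
    if (!g %in% stats$group) stopConfig("unknown group label: ", g)
  proteins <- unique(stats$protein)
  rows <- lapply(proteins, function(p) {
    pick <- function(g) {
      r <- stats[stats$protein == p & stats$group == g, ]
      if (nrow(r) != 1L)
        stopData("expected exactly one summary row for ", p, " in group ", g)
      r
    }
    rc <- pick(control); rt <- pick(treatment)
    out <- data.frame(
      protein = p,
      gene = if ("gene" %in% names(rc)) rc$gene else NA_character_,
      control_status = rc$status, control_n = rc$n,
      control_mean = rc$mean, control_sd = rc$sd, control_lloq = rc$lloq,
      treatment_status = rt$status, treatment_n = rt$n,
      treatment_mean = rt$mean, treatment_sd = rt$sd,
      treatment_lloq = rt$lloq,
      ratio = NA_real_, t_statistic = NA_real_, p_value = NA_real_,
      outliers_removed = "", stringsAsFactors = FALSE)
    if (rc$status == "quantified" && rt$status == "quantified") {
      out$ratio <- foldRatio(rt$mean, rc$mean)
      tt <- studentTSummary(rc$mean, rc$sd, rc$n, rt$mean, rt$sd, rt$n)
      out$t_statistic <- tt$t_statistic
      out$p_value <- tt$p_value
    } else {
      out$control_mean <- ifelse(rc$status == "quantified", rc$mean, NA_real_)
      out$control_sd <- ifelse(rc$status == "quantified", rc$sd, NA_real_)
      out$treatment_mean <- ifelse(rt$status == "quantified", rt$mean, NA_real_)
      out$treatment_sd <- ifelse(rt$status == "quantified", rt$sd, NA_real_)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

formatCell <- function(mean, sd, status, lloq) {
  ifelse(status == "quantified",
         paste0(signif(mean, 2), " ± ", signif(sd, 2)),
         ifelse(status == "ULQ",
                ifelse(is.na(lloq), "ULQ", paste0("<", lloq, " (ULQ)")),
                "NQ"))
}

#' Render comparison rows at publication precision
#'
#' Formats `mean +/- SD` cells at 2 significant figures, ULQ cells as
#' `"<bound (ULQ)"`, NQ cells as `"NQ"`, ratios at 2 significant figures and
#' p-values at 1 significant figure, matching the printed-table convention.
#' Full precision stays in the unformatted rows / JSON output.
#'
#' @param rows data.frame from [summarizeGroups()] or
#'   [summarizeFromStats()].
#' @return data.frame of formatted strings, one row per protein.
#' @export
formatComparisonTable <- function(rows) {
  data.frame(
    protein = rows$protein,
    gene = rows$gene,
    control = formatCell(rows$control_mean, rows$control_sd,
                         rows$control_status, rows$control_lloq),
    treatment = formatCell(rows$treatment_mean, rows$treatment_sd,
                           rows$treatment_status, rows$treatment_lloq),
    ratio = ifelse(is.na(rows$ratio), "", as.character(signif(rows$ratio, 2))),
    p_value = ifelse(is.na(rows$p_value), "",
                     as.character(signif(rows$p_value, 1))),
    stringsAsFactors = FALSE)
}

#' Write / read an expression matrix with sentinel cells
#'
#' `writeExpressionMatrix()` writes a CSV whose cells are either a numeric
#' value, `ULQ<bound>` or `NQ`, with the sample-to-group mapping in a second
#' header row; `readExpressionMatrix()` reconstructs the
#' [QtapExperiment-class] exactly (values, flags and bounds round-trip).
#'
#' @param x a [QtapExperiment-class].
#' @param path file path.
#' @return `writeExpressionMatrix()` returns `path` invisibly;
#'   `readExpressionMatrix()` returns a [QtapExperiment-class].
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "QtapExperiment"))
  ex <- exprValues(x); st <- exprStatus(x); lq <- lloqBounds(x)
  cells <- matrix(NA_character_, nrow(x), ncol(x), dimnames = dimnames(ex))
  cells[st == "quantified"] <-
    formatC(ex[st == "quantified"], digits = 15, format = "g")
  ulq <- st == "ULQ"
  cells[ulq] <- ifelse(is.na(lq[ulq]), "ULQ",
                       paste0("ULQ", formatC(lq[ulq], digits = 15,
                                             format = "g")))
  cells[st == "NQ"] <- "NQ"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("protein", colnames(ex)), collapse = ","), con)
  writeLines(paste(c("#group", sampleGroups(x)), collapse = ","), con)
  for (i in seq_len(nrow(cells)))
    writeLines(paste(c(rownames(cells)[i], cells[i, ]), collapse = ","), con)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[2], "#group"))
    stopFormat("expression matrix file lacks the '#group' mapping row")
  split1 <- strsplit(lines, ",", fixed = TRUE)
  samples <- split1[[1]][-1]
  groups <- split1[[2]][-1]
  body <- split1[-(1:2)]
  proteins <- vapply(body, `[`, "", 1L)
  dn <- list(proteins, samples)
  ex <- matrix(NA_real_, length(proteins), length(samples), dimnames = dn)
  st <- matrix("NQ", length(proteins), length(samples), dimnames = dn)
  lq <- matrix(NA_real_, length(proteins), length(samples), dimnames = dn)
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    if (length(cells) != length(samples))
      stopFormat("row ", i + 2L, ": expected ", length(samples), " cells")
    isULQ <- startsWith(cells, "ULQ")
    isNQ <- cells == "NQ"
    st[i, isULQ] <- "ULQ"
    btxt <- sub("^ULQ", "", cells[isULQ])
    bounds <- rep(NA_real_, length(btxt))
    bounds[nzchar(btxt)] <- as.numeric(btxt[nzchar(btxt)])
    lq[i, isULQ] <- bounds
    quant <- !isULQ & !isNQ
    st[i, quant] <- "quantified"
    ex[i, quant] <- as.numeric(cells[quant])
  }
  QtapExperiment(expression = ex, status = st, lloq = lq, group = groups)
}

#' Assess microvessel purity from membrane-marker expression
#'
#' Compares the endothelial luminal-membrane marker (gamma-Gtp) and the
#' abluminal plasma-membrane marker (Na/K-ATPase) between the microvessel
#' and whole-tissue matrices: reports per-group marker means, the
#' microvessel/tissue enrichment of the luminal marker (a lower bound when
#' the tissue side is ULQ), and a between-group equivalence p-value per
#' marker within the microvessel matrix.
#'
#' @param microvessels,tissue [QtapExperiment-class] objects sharing the
#'   marker proteins.
#' @param luminalMarker,abluminalMarker protein names of the two markers.
#' @return list with `markerMeans` (per matrix/marker/group), `enrichment`
#'   (ratio, `isLowerBound`), and `betweenGroupP` per marker.
#' @export
purityAssessment <- function(microvessels, tissue,
                             luminalMarker = "gGtp",
                             abluminalMarker = "NaKATPase") {
  for (m in c(luminalMarker, abluminalMarker)) {
    if (!m %in% rownames(microvessels))
      stopConfig("marker absent from microvessel matrix: ", m)
    if (!m %in% rownames(tissue))
      stopConfig("marker absent from tissue matrix: ", m)
  }
  markerRow <- function(x, marker) {
    vals <- exprValues(x)[marker, ]
    st <- exprStatus(x)[marker, ]
    grp <- sampleGroups(x)
    means <- tapply(ifelse(st == "quantified", vals, NA), grp,
                    mean, na.rm = TRUE)
    list(means = means, values = vals, status = st, grp = grp)
  }
  mvLum <- markerRow(microvessels, luminalMarker)
  tiLum <- markerRow(tissue, luminalMarker)
  mvAbl <- markerRow(microvessels, abluminalMarker)

  mvMean <- mean(mvLum$values[mvLum$status == "quantified"])
  tiQuant <- tiLum$status == "quantified"
  if (any(tiQuant)) {
    enrich <- mvMean / mean(tiLum$values[tiQuant])
    lower <- FALSE
  } else {
    bound <- suppressWarnings(
      max(lloqBounds(tissue)[luminalMarker, ], na.rm = TRUE))
    if (!is.finite(bound))
      stopData("tissue luminal marker is ULQ but carries no LLOQ bound")
    enrich <- mvMean / bound
    lower <- TRUE
  }
  betweenP <- function(mk) {
    grps <- unique(mk$grp)
    if (length(grps) < 2L) return(NA_real_)
    a <- mk$values[mk$grp == grps[1] & mk$status == "quantified"]
    b <- mk$values[mk$grp == grps[2] & mk$status == "quantified"]
    studentTRaw(a, b)$p_value
  }
  list(markerMeans = list(
         microvessel_luminal = mvLum$means,
         tissue_luminal = tiLum$means,
         microvessel_abluminal = mvAbl$means),
       enrichment = list(marker = luminalMarker, ratio = enrich,
                         isLowerBound = lower),
       betweenGroupP = c(
         stats::setNames(betweenP(mvLum), luminalMarker),
         stats::setNames(betweenP(mvAbl), abluminalMarker)))
}

#' Cross-model twofold comparison
#'
#' For every protein shared between two model comparisons (each a row set
#' from [summarizeGroups()] / [summarizeFromStats()]), computes the
#' between-model expression ratios on the disease side
#' (`treatment_mean_B / treatment_mean_A`) and the wild-type side
#' (`control_mean_B / control_mean_A`), flags ratios beyond the fold
#' `threshold` (above it or below its reciprocal), and classifies the
#' alteration via [classifyAlteration()].
#'
#' @param rowsA,rowsB comparison rows for models A and B.
#' @param threshold fold-change threshold, > 1 (default 2, the dashed-line
#'   twofold convention).
#' @param ageComparison logical; set TRUE when the two "models" are
#'   age-differing wild-type groups, so concordant differences classify as
#'   age-dependent rather than interspecies.
#' @return data.frame with `protein`, `ratio_disease`, `ratio_wildtype`,
#'   `flagged_disease`, `flagged_wildtype`, `classification`.
#' @export
crossModelFlags <- function(rowsA, rowsB, threshold = 2,
                            ageComparison = FALSE) {
  if (threshold <= 1) stopConfig("threshold: must be > 1")
  shared <- intersect(rowsA$protein, rowsB$protein)
  if (!length(shared)) {
    warnQtap("no shared proteins between the two model comparisons")
    return(data.frame(protein = character(), ratio_disease = numeric(),
                      ratio_wildtype = numeric(), flagged_disease = logical(),
                      flagged_wildtype = logical(),
                      classification = character()))
  }
  a <- rowsA[match(shared, rowsA$protein), ]
  b <- rowsB[match(shared, rowsB$protein), ]
  okD <- a$treatment_status == "quantified" & b$treatment_status == "quantified"
  okW <- a$control_status == "quantified" & b$control_status == "quantified"
  rd <- ifelse(okD, b$treatment_mean / a$treatment_mean, NA_real_)
  rw <- ifelse(okW, b$control_mean / a$control_mean, NA_real_)
  beyond <- function(r) !is.na(r) & (r >= threshold | r <= 1 / threshold)
  cls <- vapply(seq_along(shared), function(i)
    classifyAlteration(rd[i], rw[i], threshold = threshold,
                       ageComparison = ageComparison), "")
  data.frame(protein = shared, ratio_disease = rd, ratio_wildtype = rw,
             flagged_disease = beyond(rd), flagged_wildtype = beyond(rw),
             classification = cls, stringsAsFactors = FALSE)
}

#' Classify a cross-model expression difference
#'
#' Rules, at fold `threshold` (default 2):
#' \itemize{
#'   \item either ratio undefined (ULQ/NQ on one side) -> `"not-comparable"`;
#'   \item both the disease-side and wild-type-side ratios beyond the
#'     threshold in the same direction -> `"interspecies"` (or
#'     `"age-dependent"` when `ageComparison = TRUE`);
#'   \item the disease side beyond the threshold while the wild-type side is
#'     not, the converse, or both beyond in opposite directions ->
#'     `"model-specific"`;
#'   \item neither beyond the threshold -> `"none"`.
#' }
#'
#' @param ratioDisease,ratioWildtype between-model expression ratios on the
#'   disease and wild-type sides.
#' @param threshold fold threshold, > 1.
#' @param ageComparison see [crossModelFlags()].
#' @return character classification.
#' @export
classifyAlteration <- function(ratioDisease, ratioWildtype, threshold = 2,
                               ageComparison = FALSE) {
  if (threshold <= 1) stopConfig("threshold: must be > 1")
  if (is.na(ratioDisease) || is.na(ratioWildtype)) return("not-comparable")
  beyond <- function(r) r >= threshold | r <= 1 / threshold
  bD <- beyond(ratioDisease); bW <- beyond(ratioWildtype)
  if (bD && bW) {
    if (sign(log(ratioDisease)) == sign(log(ratioWildtype)))
      return(if (ageComparison) "age-dependent" else "interspecies")
    return("model-specific")
  }
  if (bD || bW) return("model-specific")
  "none"
}
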