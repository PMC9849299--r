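#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Full generative specification for synthetic QTAP-style datasets
#'
#' A `SimConfig` bundles everything the synthetic-data generators need:
#' per-protein true abundances per group (fmol/ug total protein), the
#' transition structure of each surrogate peptide, noise levels, the
#' internal-standard spike and protein load, the detection floor, and the
#' effect sizes for the companion amino-acid and qPCR generators.
#'
#' @slot seed integer RNG seed; identical seed + config yields byte-identical
#'   datasets.
#' @slot groups data.frame with columns `label`, `n` (samples per group).
#' @slot abundances numeric matrix, proteins x groups, true abundance in
#'   fmol/ug total protein (row/col names required).
#' @slot nTransitions integer, 3 or 4 MRM transitions per peptide.
#' @slot transitionFractions numeric, per-transition relative intensity
#'   weights; strictly positive, summing to 1.
#' @slot noiseCv technical (per-transition) coefficient of variation of the
#'   multiplicative log-normal area noise.
#' @slot biologicalCv between-sample abundance CV (one draw per sample).
#' @slot spikeFmol labelled-peptide spike per digest (fmol).
#' @slot proteinLoadUg total protein per digest (ug).
#' @slot detectionAreaFloor minimum peak area below which a transition is
#'   reported undetected (arbitrary area units).
#' @slot areaPerFmol detector response factor (area units per fmol on
#'   column), shared across peptides.
#' @slot aaEffects named numeric, percent-of-control effect per amino acid
#'   in the treatment group (control = 100).
#' @slot qpcrEffects named numeric, true fold change per target gene in the
#'   treatment group.
#' @slot primerEfficiency amplification efficiency (fold per cycle), in
#'   (1, 2].
#' @slot ctNoiseSd standard deviation of additive Ct noise (cycles).
#'
#' @seealso [simConfig()] for the user-facing constructor with study-scale
#'   defaults.
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    groups = "data.frame",
    abundances = "matrix",
    nTransitions = "integer",
    transitionFractions = "numeric",
    noiseCv = "numeric",
    biologicalCv = "numeric",
    spikeFmol = "numeric",
    proteinLoadUg = "numeric",
    detectionAreaFloor = "numeric",
    areaPerFmol = "numeric",
    aaEffects = "numeric",
    qpcrEffects = "numeric",
    primerEfficiency = "numeric",
    ctNoiseSd = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  g <- object@groups
  if (!all(c("label", "n") %in% names(g)))
    msg <- c(msg, "groups: must have columns 'label' and 'n'")
  else {
    if (nrow(g) < 1L) msg <- c(msg, "groups: at least one group required")
    if (any(g$n < 2L)) msg <- c(msg, "groups: n_samples must be >= 2 per group")
    if (anyDuplicated(g$label)) msg <- c(msg, "groups: labels must be unique")
  }
  a <- object@abundances
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "abundances: matrix needs protein rownames and group colnames")
  else if (all(c("label", "n") %in% names(g)) &&
           !setequal(colnames(a), g$label))
    msg <- c(msg, "abundances: column names must match group labels")
  if (any(a < 0)) msg <- c(msg, "abundances: must be >= 0")
  if (!(object@nTransitions %in% c(3L, 4L)))
    msg <- c(msg, "nTransitions: must be 3 or 4")
  f <- object@transitionFractions
  if (length(f) != object@nTransitions)
    msg <- c(msg, "transitionFractions: length must equal nTransitions")
  if (any(f <= 0)) msg <- c(msg, "transitionFractions: must be strictly positive")
  if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "transitionFractions: must sum to 1 within 1e-9")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv: must be >= 0")
  if (object@biologicalCv < 0) msg <- c(msg, "biologicalCv: must be >= 0")
  if (object@spikeFmol <= 0) msg <- c(msg, "spikeFmol: must be > 0")
  if (object@proteinLoadUg <= 0) msg <- c(msg, "proteinLoadUg: must be > 0")
  if (object@detectionAreaFloor < 0)
    msg <- c(msg, "detectionAreaFloor: must be >= 0")
  if (object@areaPerFmol <= 0) msg <- c(msg, "areaPerFmol: must be > 0")
  if (length(object@aaEffects) && is.null(names(object@aaEffects)))
    msg <- c(msg, "aaEffects: must be a named vector")
  if (length(object@qpcrEffects) && is.null(names(object@qpcrEffects)))
    msg <- c(msg, "qpcrEffects: must be a named vector")
  if (object@primerEfficiency <= 1 || object@primerEfficiency > 2)
    msg <- c(msg, "primerEfficiency: must lie in (1, 2]")
  if (object@ctNoiseSd < 0) msg <- c(msg, "ctNoiseSd: must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", nrow(object@abundances), "proteins,",
      paste(sprintf("%s (n=%d)", object@groups$label, object@groups$n),
            collapse = " vs "), "\n")
  cat("  transitions/peptide:", object@nTransitions,
      " fractions:", paste(object@transitionFractions, collapse = "/"), "\n")
  cat("  technical CV:", object@noiseCv, " biological CV:",
      object@biologicalCv, "\n")
  cat("  spike:", object@spikeFmol, "fmol; load:", object@proteinLoadUg,
      "ug; detection floor:", object@detectionAreaFloor, "area units\n")
  cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## QtapExperiment
## ---------------------------------------------------------------------------

#' Absolute protein expression matrix with ULQ/NQ flags
#'
#' `QtapExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' three parallel assays describing a proteins x samples absolute-expression
#' grid:
#' \describe{
#'   \item{`expression`}{numeric, fmol/ug total protein; `NA` wherever the
#'     cell is not quantified.}
#'   \item{`status`}{character, one of `"quantified"`, `"ULQ"` (under limit
#'     of quantification: fewer than 3 transitions observed), `"NQ"` (not
#'     quantified/investigated in this dataset).}
#'   \item{`lloq`}{numeric lower-limit-of-quantification bound attached to
#'     ULQ cells for report rendering (`NA` elsewhere).}
#' }
#' `colData` carries the sample-to-group mapping in its `group` column.
#'
#' @seealso [buildExpressionMatrix()], [exprValues()], [summarizeGroups()]
#' @export
setClass("QtapExperiment", contains = "SummarizedExperiment")

setValidity("QtapExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("expression", "status", "lloq")
  if (!all(need %in% an))
    return(paste("assays must include:", paste(need, collapse = ", ")))
  st <- assay(object, "status")
  ex <- assay(object, "expression")
  if (!all(st %in% c("quantified", "ULQ", "NQ")))
    msg <- c(msg, "status cells must be one of quantified/ULQ/NQ")
  if (any(is.na(ex) & st == "quantified") ||
      any(!is.na(ex) & st != "quantified"))
    msg <- c(msg, "expression must be non-NA exactly where status is 'quantified'")
  if (!("group" %in% names(colData(object))))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a QtapExperiment from assay matrices
#'
#' @param expression numeric proteins x samples matrix (NA where not
#'   quantified), with dimnames.
#' @param status character matrix of the same shape with cells
#'   `"quantified"`, `"ULQ"` or `"NQ"`.
#' @param lloq numeric matrix of LLOQ bounds (NA where not applicable). A
#'   single named-per-protein vector is recycled across samples.
#' @param group character or factor of group labels, one per sample.
#' @param gene optional per-protein gene symbols stored in `rowData`.
#' @return A [QtapExperiment-class] object.
#' @export
QtapExperiment <- function(expression, status, lloq = NULL, group, gene = NULL) {
  if (is.null(lloq)) {
    lloq <- matrix(NA_real_, nrow(expression), ncol(expression),
                   dimnames = dimnames(expression))
  } else if (is.vector(lloq)) {
    lloq <- matrix(rep(lloq, ncol(expression)), nrow(expression),
                   dimnames = dimnames(expression))
  }
  cd <- DataFrame(group = as.character(group), row.names = colnames(expression))
  rd <- if (is.null(gene)) DataFrame(row.names = rownames(expression))
        else DataFrame(gene = gene, row.names = rownames(expression))
  se <- SummarizedExperiment(
    assays = SimpleList(expression = expression, status = status, lloq = lloq),
    colData = cd, rowData = rd)
  new("QtapExperiment", se)
}

#' @rdname QtapExperiment-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname QtapExperiment-accessors
#' @export
setGeneric("exprStatus", function(x) standardGeneric("exprStatus"))
#' @rdname QtapExperiment-accessors
#' @export
setGeneric("lloqBounds", function(x) standardGeneric("lloqBounds"))
#' @rdname QtapExperiment-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Accessors for QtapExperiment assays
#'
#' `exprValues()` returns the numeric fmol/ug matrix (NA where not
#' quantified); `exprStatus()` the quantified/ULQ/NQ flag matrix;
#' `lloqBounds()` the LLOQ bound matrix; `sampleGroups()` the named
#' sample-to-group vector.
#'
#' @param x a [QtapExperiment-class].
#' @return A matrix (or named character vector for `sampleGroups`).
#' @name QtapExperiment-accessors
NULL

#' @rdname QtapExperiment-accessors
#' @export
setMethod("exprValues", "QtapExperiment", function(x) assay(x, "expression"))
#' @rdname QtapExperiment-accessors
#' @export
setMethod("exprStatus", "QtapExperiment", function(x) assay(x, "status"))
#' @rdname QtapExperiment-accessors
#' @export
setMethod("lloqBounds", "QtapExperiment", function(x) assay(x, "lloq"))
#' @rdname QtapExperiment-accessors
#' @export
setMethod("sampleGroups", "QtapExperiment", function(x) {
  structure(as.character(colData(x)$group), names = colnames(x))
})

setMethod("show", "QtapExperiment", function(object) {
  st <- exprStatus(object)
  cat("QtapExperiment:", nrow(object), "proteins x", ncol(object), "samples",
      "(fmol/ug total protein)\n")
  tb <- table(factor(sampleGroups(object)))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)),
                         collapse = ", "), "\n")
  cat("  cells: ", sum(st == "quantified"), " quantified, ",
      sum(st == "ULQ"), " ULQ, ", sum(st == "NQ"), " NQ\n", sep = "")
})
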