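## Synthetic-data module: transition-level MRM datasets, amino-acid
## analyte/IS tables and qPCR Ct tables with known ground truth.

#' Default transporter panel abundances (fmol/ug total protein)
#'
#' True abundances for an 18-transporter blood-brain-barrier panel plus the
#' two membrane purity markers (gamma-Gtp, luminal endothelial; Na/K-ATPase,
#' abluminal plasma membrane), on the scale reported for crude membrane
#' fractions of isolated mouse cerebral microvessels in a wild-type vs
#' 5xFAD-model comparison. CAT-1 and OCT1 sit below the default detection
#' limit, so the generated datasets reproduce the ULQ failure mode.
#'
#' @return numeric matrix, proteins x groups (`WT`, `5xFAD`).
#' @export
transporterPanel <- function() {
  p <- rbind(
    Abcb1    = c(3.1,   2.2),
    Abcg2    = c(1.1,   1.1),
    Abcc1    = c(0.065, 0.068),
    Abcc4    = c(0.13,  0.16),
    Abca1    = c(0.092, 0.097),
    ASCT1    = c(0.71,  1.5),
    GLUT1    = c(46,    49),
    `4F2hc`  = c(0.50,  0.72),
    `CAT-1`  = c(0.005, 0.005),
    LAT1     = c(0.32,  0.12),
    MCT1     = c(0.11,  0.097),
    RFC      = c(0.088, 0.099),
    OATP1A4  = c(0.36,  0.49),
    OATP1C1  = c(0.14,  0.14),
    OCT1     = c(0.005, 0.005),
    OAT3     = c(0.31,  0.47),
    FATP1    = c(0.13,  0.086),
    ENT1     = c(0.19,  0.18),
    gGtp     = c(2.9,   2.5),
    NaKATPase = c(29,   26))
  colnames(p) <- c("WT", "5xFAD")
  p
}

#' Amino-acid percent-of-control effect presets
#'
#' Treatment-group effects (percent above control) for the seven measured
#' LAT1/ASCT1 substrate amino acids, at the magnitudes reported for an AD
#' mouse model: in brain cortex serine +20, phenylalanine +13, histidine
#' +30; in plasma alanine +39, leucine +30, phenylalanine +16.
#'
#' @return named numeric vector of percent effects.
#' @export
brainAminoAcidEffects <- function() {
  c(serine = 20, alanine = 0, phenylalanine = 13, histidine = 30,
    leucine = 0, isoleucine = 0, tyrosine = 0)
}

#' @rdname brainAminoAcidEffects
#' @export
plasmaAminoAcidEffects <- function() {
  c(serine = 0, alanine = 39, phenylalanine = 16, histidine = 0,
    leucine = 30, isoleucine = 0, tyrosine = 0)
}

#' Create a simulation configuration
#'
#' Builds a validated [SimConfig-class]. Defaults emulate the measurement
#' structure of a two-group (wild-type vs transgenic) QTAP study of brain
#' microvessel transporters: n = 6 per group, 4 transitions per surrogate
#' peptide, 50 ug protein digests spiked with 10 fmol labelled peptide,
#' log-normal technical noise (CV 0.1) on top of between-animal biological
#' variation (CV 0.3), and a hard per-transition detection floor.
#'
#' @param seed integer RNG seed.
#' @param groups data.frame with columns `label` and `n`.
#' @param abundances proteins x groups matrix of true abundances (fmol/ug);
#'   defaults to [transporterPanel()].
#' @param nTransitions 3 or 4 transitions per peptide.
#' @param transitionFractions per-transition relative intensities (sum 1).
#' @param noiseCv technical CV of multiplicative log-normal area noise.
#' @param biologicalCv between-sample abundance CV.
#' @param spikeFmol labelled-peptide spike per digest (fmol).
#' @param proteinLoadUg total protein per digest (ug).
#' @param detectionAreaFloor minimum detectable peak area (area units).
#' @param areaPerFmol detector response factor (area units per fmol).
#' @param aaEffects named percent-of-control amino-acid effects
#'   (default [brainAminoAcidEffects()]).
#' @param qpcrEffects named true fold changes per qPCR target gene.
#' @param primerEfficiency amplification efficiency in (1, 2].
#' @param ctNoiseSd additive Ct noise SD (cycles).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7, noiseCv = 0, biologicalCv = 0)
#' sim <- simulateMrmDataset(cfg)
#' head(sim$transitions)
#' @export
simConfig <- function(seed = 1L,
                      groups = data.frame(label = c("WT", "5xFAD"),
                                          n = c(6L, 6L)),
                      abundances = transporterPanel(),
                      nTransitions = 4L,
                      transitionFractions = c(0.4, 0.3, 0.2, 0.1),
                      noiseCv = 0.1,
                      biologicalCv = 0.3,
                      spikeFmol = 10,
                      proteinLoadUg = 50,
                      detectionAreaFloor = 150,
                      areaPerFmol = 1000,
                      aaEffects = brainAminoAcidEffects(),
                      qpcrEffects = c(Gfap = 4, Aif1 = 3, Il1b = 2),
                      primerEfficiency = 2,
                      ctNoiseSd = 0.2) {
  if (is.data.frame(abundances)) abundances <- as.matrix(abundances)
  if (missing(abundances)) {
    # adapt the default panel to the configured groups: match labels by
    # position for a two-group design, otherwise replicate the first column
    if (nrow(groups) == 2L) {
      colnames(abundances) <- groups$label
    } else {
      abundances <- abundances[, rep(1L, nrow(groups)), drop = FALSE]
      colnames(abundances) <- groups$label
    }
  }
  cfg <- try(new("SimConfig",
    seed = as.integer(seed), groups = groups, abundances = abundances,
    nTransitions = as.integer(nTransitions),
    transitionFractions = transitionFractions,
    noiseCv = noiseCv, biologicalCv = biologicalCv,
    spikeFmol = spikeFmol, proteinLoadUg = proteinLoadUg,
    detectionAreaFloor = detectionAreaFloor, areaPerFmol = areaPerFmol,
    aaEffects = aaEffects, qpcrEffects = qpcrEffects,
    primerEfficiency = primerEfficiency, ctNoiseSd = ctNoiseSd),
    silent = TRUE)
  if (inherits(cfg, "try-error"))
    stopConfig("invalid simulation configuration: ",
               sub(".*invalid class .SimConfig. object: ", "",
                   trimws(attr(cfg, "condition")$message)))
  cfg
}

## Multiplicative log-normal factor with mean 1 and coefficient of
## variation cv: sigma^2 = log(1 + cv^2), meanlog = -sigma^2/2.
lnormFactor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

sampleDesign <- function(config) {
  g <- config@groups
  data.frame(
    sample_id = unlist(mapply(function(lab, n) sprintf("%s_%02d", lab, seq_len(n)),
                              g$label, g$n, SIMPLIFY = FALSE), use.names = FALSE),
    group = rep(g$label, g$n),
    stringsAsFactors = FALSE)
}

#' Generate a transition-level MRM dataset with ground truth
#'
#' For every sample and protein, emits paired light/heavy records for each
#' MRM transition of the protein's surrogate peptide. Heavy (internal
#' standard) areas reflect `spikeFmol x fraction x response x noise`; light
#' (endogenous) areas reflect
#' `trueAbundance x proteinLoadUg x fraction x response x noise`, where the
#' per-sample true abundance is the group mean perturbed by log-normal
#' biological variation. A transition whose area falls below
#' `detectionAreaFloor` is emitted with `detected = FALSE`.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return list with components:
#'   \describe{
#'     \item{`transitions`}{data.frame with columns `sample_id`, `group`,
#'       `protein`, `peptide`, `transition_id`, `label`, `peak_area`,
#'       `detected`.}
#'     \item{`spikeLoad`}{per-sample `spike_fmol` / `protein_load_ug` table.}
#'     \item{`design`}{sample-to-group mapping.}
#'     \item{`truth`}{per (protein, sample) true abundance (fmol/ug).}
#'   }
#' @export
simulateMrmDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  des <- sampleDesign(config)
  prot <- rownames(config@abundances)
  nT <- config@nTransitions
  frac <- config@transitionFractions

  ## one biological abundance draw per (protein, sample)
  truth <- expand.grid(protein = prot, sample_id = des$sample_id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$group <- des$group[match(truth$sample_id, des$sample_id)]
  mu <- config@abundances[cbind(truth$protein, truth$group)]
  truth$true_abundance <- mu * lnormFactor(nrow(truth), config@biologicalCv)

  ## expand to transitions x {light, heavy}
  idx <- rep(seq_len(nrow(truth)), each = nT)
  base <- data.frame(
    sample_id = truth$sample_id[idx],
    group = truth$group[idx],
    protein = truth$protein[idx],
    peptide = paste0(truth$protein[idx], "_pep"),
    transition_id = rep(sprintf("t%d", seq_len(nT)), nrow(truth)),
    fraction = rep(frac, nrow(truth)),
    stringsAsFactors = FALSE)

  lightAmount <- truth$true_abundance[idx] * config@proteinLoadUg
  heavyAmount <- config@spikeFmol
  mkAreas <- function(amount) {
    amount * base$fraction * config@areaPerFmol *
      lnormFactor(nrow(base), config@noiseCv)
  }
  light <- base; light$label <- "light"; light$peak_area <- mkAreas(lightAmount)
  heavy <- base; heavy$label <- "heavy"; heavy$peak_area <- mkAreas(heavyAmount)
  tr <- rbind(light, heavy)
  tr$fraction <- NULL
  tr$detected <- tr$peak_area >= config@detectionAreaFloor & tr$peak_area > 0
  ord <- order(match(tr$sample_id, des$sample_id), tr$protein,
               tr$transition_id, tr$label)
  tr <- tr[ord, ]
  rownames(tr) <- NULL

  list(transitions = tr,
       spikeLoad = data.frame(sample_id = des$sample_id,
                              spike_fmol = config@spikeFmol,
                              protein_load_ug = config@proteinLoadUg,
                              stringsAsFactors = FALSE),
       design = des,
       truth = truth)
}

#' Generate an amino-acid analyte/internal-standard peak-area dataset
#'
#' The first configured group is the control, centred at 100 percent; the
#' remaining groups are centred at `100 + effect` percent per amino acid
#' (effects from `config@aaEffects`). Analyte/IS area ratios carry
#' multiplicative log-normal noise at `noiseCv`.
#'
#' @param config a [SimConfig-class]; `aaEffects` must name every simulated
#'   amino acid.
#' @param matrix `"brain"` (normalizer: mg tissue) or `"plasma"`
#'   (normalizer: uL plasma).
#' @return list with `measurements` (sample_id, group, analyte,
#'   analyte_area, is_area, matrix, normalizer) and `truth` (per analyte
#'   true percent of control per group).
#' @export
simulateAminoAcidDataset <- function(config, matrix = c("brain", "plasma")) {
  stopifnot(is(config, "SimConfig"))
  matrix <- match.arg(matrix)
  if (!length(config@aaEffects))
    stopConfig("aaEffects: no amino-acid effects configured")
  set.seed(config@seed + 1L)
  des <- sampleDesign(config)
  control <- config@groups$label[1]
  aa <- names(config@aaEffects)
  m <- expand.grid(analyte = aa, sample_id = des$sample_id,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m$group <- des$group[match(m$sample_id, des$sample_id)]
  effect <- ifelse(m$group == control, 0, config@aaEffects[m$analyte])
  isArea <- 1e5
  baseRatio <- 0.8                       # arbitrary control-level area ratio
  m$is_area <- isArea
  m$analyte_area <- isArea * baseRatio * (1 + effect / 100) *
    lnormFactor(nrow(m), config@noiseCv)
  m$matrix <- matrix
  m$normalizer <- if (matrix == "brain") 15 else 20   # mg tissue / uL plasma
  truth <- data.frame(analyte = rep(aa, each = nrow(config@groups)),
                      group = rep(config@groups$label, length(aa)),
                      stringsAsFactors = FALSE)
  truth$true_percent_of_control <-
    ifelse(truth$group == control, 100, 100 + config@aaEffects[truth$analyte])
  list(measurements = m[, c("sample_id", "group", "analyte", "analyte_area",
                            "is_area", "matrix", "normalizer")],
       truth = truth)
}

#' Generate a qPCR Ct dataset with ground truth
#'
#' Emits Ct values for the configured target genes plus a housekeeping gene
#' (`Gapdh`, true fold 1 in every group):
#' `Ct = baseline + sampleOffset - log_E(fold) + noise`, where E is the
#' primer efficiency, the per-sample offset models RNA-input differences
#' (cancelled by housekeeping normalization), and the first configured group
#' is the calibrator with fold 1.
#'
#' @param config a [SimConfig-class]; `primerEfficiency` must lie in (1, 2].
#' @param sampleOffsetSd SD of the per-sample global Ct offset (cycles).
#' @return list with `ct` (sample_id, group, gene, ct, is_housekeeping,
#'   efficiency) and `truth` (true fold per gene and group).
#' @export
simulateQpcrDataset <- function(config, sampleOffsetSd = 0.3) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed + 2L)
  des <- sampleDesign(config)
  control <- config@groups$label[1]
  genes <- c(names(config@qpcrEffects), "Gapdh")
  baseline <- c(stats::setNames(rep(28, length(config@qpcrEffects)),
                                names(config@qpcrEffects)), Gapdh = 20)
  offset <- stats::rnorm(nrow(des), 0, sampleOffsetSd)
  names(offset) <- des$sample_id
  d <- expand.grid(gene = genes, sample_id = des$sample_id,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$group <- des$group[match(d$sample_id, des$sample_id)]
  fold <- ifelse(d$gene == "Gapdh" | d$group == control,
                 1, config@qpcrEffects[d$gene])
  d$ct <- baseline[d$gene] + offset[d$sample_id] -
    log(fold) / log(config@primerEfficiency) +
    stats::rnorm(nrow(d), 0, config@ctNoiseSd)
  d$is_housekeeping <- d$gene == "Gapdh"
  d$efficiency <- config@primerEfficiency
  truth <- data.frame(gene = rep(genes, each = nrow(config@groups)),
                      group = rep(config@groups$label, length(genes)),
                      stringsAsFactors = FALSE)
  truth$true_fold <- ifelse(truth$gene == "Gapdh" | truth$group == control,
                            1, config@qpcrEffects[truth$gene])
  list(ct = d[, c("sample_id", "group", "gene", "ct", "is_housekeeping",
                  "efficiency")],
       truth = truth)
}
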