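## File formats, run configuration and the stage-chaining pipeline
## (simulate -> quantify -> compare -> report). Interchange format is plain
## delimited text; machine-readable outputs get JSON sidecars.

#' Read a transition-level peak-area table
#'
#' Reads the documented CSV header (`sample_id, group, protein, peptide,
#' transition_id, label, peak_area, detected`; `group` optional). Malformed
#' rows (negative area, unknown label, missing fields) are not silently
#' dropped: they are removed from the returned table and collected, with
#' their line numbers and reasons, in the `"rejected"` attribute.
#'
#' @param path CSV file path.
#' @return data.frame of validated transition records; the `"rejected"`
#'   attribute holds a data.frame with `line` and `reason`.
#' @export
readTransitionTable <- function(path) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "protein", "peptide", "transition_id", "label",
            "peak_area", "detected")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopFormat("transition table lacks required column(s): ",
               paste(miss, collapse = ", "))
  d$peak_area <- suppressWarnings(as.numeric(d$peak_area))
  d$detected <- as.logical(d$detected)
  reason <- rep(NA_character_, nrow(d))
  reason[is.na(d$peak_area)] <- "peak_area not numeric"
  reason[!is.na(d$peak_area) & d$peak_area < 0] <- "negative peak_area"
  reason[!d$label %in% c("light", "heavy")] <- "label not light/heavy"
  reason[is.na(d$detected)] <- "detected not logical"
  bad <- !is.na(reason)
  rejected <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                         reason = reason[bad], stringsAsFactors = FALSE)
  if (nrow(rejected))
    warnQtap(nrow(rejected), " malformed row(s) rejected; see the ",
             "'rejected' attribute for line numbers")
  out <- d[!bad, ]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' @rdname readTransitionTable
#' @param records transition record data.frame to write.
#' @export
writeTransitionTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-sample spike/load table
#'
#' @param path CSV with columns `sample_id`, `spike_fmol`,
#'   `protein_load_ug`.
#' @return validated data.frame.
#' @export
readSpikeLoadTable <- function(path) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "spike_fmol", "protein_load_ug"), names(d))
  if (length(miss))
    stopFormat("spike/load table lacks required column(s): ",
               paste(miss, collapse = ", "))
  if (any(d$spike_fmol <= 0) || any(d$protein_load_ug <= 0))
    stopData("spike_fmol and protein_load_ug must be > 0")
  d
}

#' Read a pipeline run configuration (YAML)
#'
#' @param path YAML file; see [runPipeline()] for the recognized keys.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopFormat("run configuration must be a YAML mapping")
  cfg
}

simConfigFromList <- function(sim, seed) {
  args <- list()
  if (!is.null(sim$groups))
    args$groups <- data.frame(label = vapply(sim$groups, `[[`, "", "label"),
                              n = vapply(sim$groups, function(g) {
                                # accept n_samples or n (YAML 1.1 reads a
                                # bare `n` key as a boolean)
                                v <- g[["n_samples"]]
                                if (is.null(v)) v <- g[["n"]]
                                if (is.null(v)) v <- g[["FALSE"]]
                                if (is.null(v))
                                  stopConfig("groups: each group needs ",
                                             "'label' and 'n_samples'")
                                as.integer(v)
                              }, 1L))
  if (!is.null(sim$abundances)) {
    if (!length(sim$abundances)) stopConfig("empty protein panel")
    ab <- do.call(rbind, lapply(sim$abundances, unlist))
    rownames(ab) <- names(sim$abundances)
    args$abundances <- ab
  }
  for (k in c("nTransitions", "transitionFractions", "noiseCv",
              "biologicalCv", "spikeFmol", "proteinLoadUg",
              "detectionAreaFloor", "areaPerFmol", "primerEfficiency",
              "ctNoiseSd"))
    if (!is.null(sim[[k]])) args[[k]] <- sim[[k]]
  for (k in c("aaEffects", "qpcrEffects"))
    if (!is.null(sim[[k]])) args[[k]] <- unlist(sim[[k]])
  args$seed <- seed
  do.call(simConfig, args)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Run the full pipeline
#'
#' Chains the stages: obtain transition data (either by simulation from the
#' `simulate` section or from `transitions`/`spike_load` CSV paths),
#' quantify to an expression matrix, compare the two configured groups, and
#' write the report bundle (expression matrix CSV + JSON sidecar,
#' comparison table in full precision and publication formatting, optional
#' amino-acid and qPCR comparisons, and a run manifest recording the seed,
#' settings and per-protein decisions). Outputs are deterministic: the same
#' configuration and seed yield a byte-identical bundle.
#'
#' Recognized configuration keys: `seed`; `simulate` (SimConfig fields);
#' `transitions`, `spike_load`, `design` (CSV paths, used when `simulate`
#' is absent); `control`, `treatment` (group labels; default the first two
#' groups); `stats` (`rout_q`, `min_quantified`); `lloq` (mapping protein ->
#' bound); `amino_acids`, `qpcr` (logical, simulate-and-analyze the
#' companion datasets).
#'
#' @param config configuration list (see [readRunConfig()]).
#' @param outDir output directory, created if missing.
#' @return invisibly, a list with the in-memory results (`experiment`,
#'   `comparison`, optional `aminoAcids`, `qpcr`, `manifest`).
#' @export
runPipeline <- function(config, outDir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)),
                          class = class(e)[class(e) != "simpleError"]))
    })
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package = "qtap",
                   version = as.character(utils::packageVersion("qtap")),
                   seed = seed, settings = config)

  lloqTable <- NULL
  if (!is.null(config$lloq))
    lloqTable <- data.frame(protein = names(config$lloq),
                            lloq = unlist(config$lloq))

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- simConfigFromList(config$simulate, seed)
      if (!nrow(sc@abundances)) stopConfig("empty protein panel")
      simulateMrmDataset(sc)
    })
    transitions <- sim$transitions
    spikeLoad <- sim$spikeLoad
    design <- sim$design
    writeTransitionTable(transitions, file.path(outDir, "transitions.csv"))
    utils::write.csv(sim$truth, file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    transitions <- stage("read", readTransitionTable(config$transitions))
    spikeLoad <- stage("read", readSpikeLoadTable(config$spike_load))
    design <- stage("read", {
      d <- utils::read.csv(config$design, stringsAsFactors = FALSE)
      if (!all(c("sample_id", "group") %in% names(d)))
        stopFormat("design table lacks required column(s): sample_id, group")
      d
    })
  }

  qe <- stage("quantify", {
    quants <- quantifyTransitions(transitions, spikeLoad,
                                  lloqTable = lloqTable)
    buildExpressionMatrix(quants, design)
  })
  writeExpressionMatrix(qe, file.path(outDir, "expression_matrix.csv"))
  writeJson(list(proteins = rownames(qe), samples = colnames(qe),
                 groups = as.list(sampleGroups(qe)),
                 status = apply(exprStatus(qe), 1, as.list)),
            file.path(outDir, "expression_matrix.json"))

  groups <- unique(design$group)
  control <- if (is.null(config$control)) groups[1] else config$control
  treatment <- if (is.null(config$treatment)) groups[2] else config$treatment
  routQ <- if (is.null(config$stats$rout_q)) 0.01 else config$stats$rout_q
  minQ <- if (is.null(config$stats$min_quantified)) 2L
          else as.integer(config$stats$min_quantified)
  comparison <- stage("compare",
    summarizeGroups(qe, control, treatment, routQ = routQ,
                    minQuantified = minQ))
  utils::write.csv(comparison, file.path(outDir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(formatComparisonTable(comparison),
                   file.path(outDir, "comparison_formatted.csv"),
                   row.names = FALSE)
  writeJson(comparison, file.path(outDir, "comparison.json"))

  results <- list(experiment = qe, comparison = comparison)

  if (isTRUE(config$amino_acids) && !is.null(config$simulate)) {
    results$aminoAcids <- stage("amino-acids", {
      sc <- simConfigFromList(config$simulate, seed)
      aa <- simulateAminoAcidDataset(sc)
      lv <- relativeQuantify(aa$measurements, control)
      compareAminoAcids(lv, control, treatment)
    })
    utils::write.csv(results$aminoAcids,
                     file.path(outDir, "amino_acids.csv"), row.names = FALSE)
  }
  if (isTRUE(config$qpcr) && !is.null(config$simulate)) {
    results$qpcr <- stage("qpcr", {
      sc <- simConfigFromList(config$simulate, seed)
      qp <- simulateQpcrDataset(sc)
      fe <- normalizedFoldExpression(qp$ct, control)
      compareFoldExpression(fe, control, treatment)
    })
    utils::write.csv(results$qpcr, file.path(outDir, "qpcr.csv"),
                     row.names = FALSE)
  }

  manifest$decisions <- lapply(seq_len(nrow(comparison)), function(i) {
    r <- comparison[i, ]
    list(protein = r$protein,
         control_status = r$control_status,
         treatment_status = r$treatment_status,
         outliers_removed =
           if (nzchar(r$outliers_removed))
             strsplit(r$outliers_removed, ",")[[1]] else list())
  })
  writeJson(manifest, file.path(outDir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}
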