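# Hand-built transition records and small configs shared across tests.

# One peptide in one sample: light/heavy rows per transition with the given
# light/heavy area ratios (heavy area fixed at `heavy`).
makeRecords <- function(ratios, sample = "s1", protein = "P1",
                        peptide = "P1_pep", heavy = 1000,
                        lightDetected = TRUE, heavyDetected = TRUE) {
  nT <- length(ratios)
  data.frame(
    sample_id = sample, protein = protein, peptide = peptide,
    transition_id = rep(sprintf("t%d", seq_len(nT)), 2),
    label = rep(c("light", "heavy"), each = nT),
    peak_area = c(ratios * heavy, rep(heavy, nT)),
    detected = c(rep_len(lightDetected, nT), rep_len(heavyDetected, nT)),
    stringsAsFactors = FALSE)
}

# Two-group config around a single protein with configurable abundances.
oneProteinConfig <- function(seed, wt, ad, n = 6L, noiseCv = 0.1,
                             biologicalCv = 0.3, ...) {
  simConfig(seed = seed,
            groups = data.frame(label = c("WT", "AD"), n = c(n, n)),
            abundances = matrix(c(wt, ad), 1, 2,
                                dimnames = list("P1", c("WT", "AD"))),
            noiseCv = noiseCv, biologicalCv = biologicalCv, ...)
}

# Independent re-implementation of the robust FDR outlier screen, used as a
# brute-force oracle against routOutliers().
routOracle <- function(x, q) {
  n <- length(x)
  r <- x - median(x)
  rsdr <- unname(quantile(abs(r), 0.6827, type = 7)) * n / (n - 1)
  if (q == 0 || rsdr == 0) return(integer())
  maxFlag <- floor(0.3 * n)
  if (maxFlag < 1) return(integer())
  ord <- order(abs(r), decreasing = TRUE)[seq_len(maxFlag)]
  p <- 2 * pt(-abs(r[ord]) / rsdr, df = n - 2)
  pass <- which(p < q * seq_len(maxFlag) / n)
  if (!length(pass)) return(integer())
  sort(ord[seq_len(max(pass))])
}
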