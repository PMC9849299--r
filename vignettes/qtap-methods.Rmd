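---
title: "Absolute transporter quantification from MRM transitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute transporter quantification from MRM transitions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtap)
```

This vignette explains the models behind the package: how absolute
protein expression is computed from stable-isotope-dilution MRM
transition areas, what the statistical layer assumes, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The quantification model

Each target protein is represented by a single proteotypic peptide
monitored over 3–4 MRM transitions in two isotope channels. For a
transition *t* whose light (endogenous) and heavy (internal standard)
peaks are both detected, the per-transition quantitative value is

$$v_t = \frac{A^{light}_t}{A^{heavy}_t} \cdot
        \frac{\mathrm{spike}\ (\mathrm{fmol})}{\mathrm{load}\ (\mu g)}
        \quad [\mathrm{fmol}/\mu g\ \mathrm{total\ protein}].$$

Protein expression is the unweighted arithmetic mean of the contributing
$v_t$. The averaging rule is deliberately simple: the field convention
reports "the average" of the transition values without intensity
weighting, and an unweighted mean keeps the estimator transparent and
scale-equivariant (multiplying all light areas by *c* multiplies
expression by *c*; doubling the protein load halves it — both are tested
invariants).

**ULQ rule.** A transition pair contributes only when *both* channels are
detected; the ratio is undefined otherwise. With two or fewer
contributing transitions the protein is reported **ULQ** (under the limit
of quantification) — a categorical outcome, not a censored number. ULQ
cells carry a per-protein **LLOQ** bound for rendering
(`<0.15 (ULQ)`-style sentinels) and are excluded from group means and
tests. **NQ** marks proteins not measured in a dataset at all. Every
matrix cell is exactly one of value / ULQ / NQ, enforced by the
`QtapExperiment` validity method.

**LLOQ.** The lower limit of quantification is defined operationally from
a dilution series of the labelled peptide: the lowest level producing
signal peaks with 3–4 transitions. `determineLloq()` applies the rule
verbatim; a non-monotone series (a qualifying level below a failing one)
is flagged with a warning but still returns the lowest qualifying level,
since the definition does not say otherwise. Detection itself is decided
upstream of this package (peak integration software); the pipeline starts
from areas plus detected flags, and the simulator models detection as a
hard area floor.

## The statistical layer

**Test choice.** Group differences use the unpaired two-sided Student's
*t*-test with pooled variance, not Welch. The choice is empirical:
recomputing p-values from the published mean ± SD ± n summaries of the
transporter tables reproduces the printed values (e.g. 0.008 for LAT1 and
0.01 for ASCT1 in microvessels) under pooling, while Welch degrees of
freedom do not. The summary-statistic form `studentTSummary()` is
algebraically identical to the raw form (tested to 1e-12) and exists so
printed tables are first-class inputs. No multiple-testing correction is
applied across the transporter panel, matching the source convention;
users comparing many proteins should keep this in mind.

**Outlier screen.** The screen named "ROUT" in GraphPad is proprietary
and undocumented; `routOutliers()` implements a documented univariate
variant with the same structure: robust location = median; robust scale
(RSDR) = the 68.27th percentile of absolute residuals (the Gaussian
1-sigma point) with an $n/(n-1)$ small-sample correction; candidates =
the largest residuals (at most 30 % of the sample); flagging by a
Benjamini–Hochberg-style step on two-sided *t* tail probabilities
($df = n-2$) at FDR Q, default Q = 1 %. `q = 0` flags nothing by
construction. On clean normal data at n = 6 the screen flags anything in
well under 5 % of datasets (tested by simulation); every removal is
recorded in the result and in the run manifest. Whether published tables
were computed before or after outlier removal is not stated in the
sources this design follows, so removal is explicit and configurable
(`routQ = NA` disables it).

**Power and sample size.** `powerTwoSampleT()` uses the exact
noncentral-*t* distribution: $df = 2n-2$, noncentrality
$|\delta|/(s_p\sqrt{2/n})$ with $s_p = \sqrt{(s_1^2+s_2^2)/2}$, power
$= P(|T'| > t_{1-\alpha/2})$. For the anchoring example (group means 0.12
vs 0.37, SDs 0.040 and 0.18) the power is 0.757 at n = 5 and 0.848 at
n = 6, so the minimum n at 80 % power is 6 — matching the design it
reproduces, and agreeing with a direct Monte-Carlo simulation of the
pooled test to within 0.01 despite the unequal group SDs. `delta = 0` is
allowed in the power function (it returns the test's size, α) but
rejected by `minSampleSize()`, whose search would not terminate.

## The synthetic-data generator

The generator is the package's ground-truth instrument; its defaults are
the study conditions it emulates, chosen once:

- **Design**: two groups (wild-type vs transgenic), n = 6 per group for
  microvessel-style runs; cortex-style runs use 14/12.
- **Panel**: 18 transporters plus two membrane markers at the abundance
  scale of crude-membrane transporter profiling (≈0.005–50 fmol/µg),
  including a true twofold ASCT1 increase and a LAT1 decrease.
- **Peptide model**: 4 transitions with relative intensities
  0.4/0.3/0.2/0.1; 50 µg digests spiked with 10 fmol labelled peptide.
- **Noise**: multiplicative log-normal at two levels — biological
  variation per sample (CV 0.3) and technical variation per transition
  (CV 0.1), with $\sigma^2 = \ln(1+CV^2)$ and mean-one scaling. Areas are
  positive and right-skewed, the standard error structure for MS peak
  areas. Both levels are needed to reproduce table-scale group SDs; the
  sources do not report the split, so the defaults are free parameters
  documented here.
- **Detection**: a hard per-transition area floor (150 area units against
  a shared response factor of 1000 area units/fmol). At a 50 µg load the
  weakest quantifying transition (20 % relative intensity) crosses the
  floor at 0.015 fmol/µg — the implied LLOQ — which yields the realistic
  "only two or one transitions" failure mode at low abundance. The two
  panel proteins set below this floor (0.005 fmol/µg) make default
  datasets exercise the ULQ path.

The companion generators mirror the measurement structure of the other
assays: amino-acid analyte/IS area ratios centred at 100 % for controls
and $100 + \mathrm{effect}$ for treatment (default effects at the
reported percent-of-control magnitudes: brain serine +20 %, phenylalanine
+13 %, histidine +30 %; plasma alanine +39 %, leucine +30 %,
phenylalanine +16 %), and qPCR Ct values
$Ct = \mathrm{baseline} + \mathrm{sampleOffset} - \log_E(\mathrm{fold}) +
\varepsilon$ with a housekeeping gene at fold 1, a per-sample RNA-input
offset that must cancel in ΔCt, and efficiency $E \in (1, 2]$.

What the simulator does **not** model: chromatography (no retention-time
drift or peak-shape effects), transition interference and cross-talk,
per-peptide response-factor differences, correlated noise across
transitions, and matrix effects. Passing tests on synthetic data
therefore demonstrate that the computational pipeline is correct under
its stated error model — unbiased recovery of true abundances, fold
changes and effect sizes, correct ULQ behaviour, nominal type-I error —
not that any particular instrument's data meet that model.

## Numerical and reporting choices

- Full precision is retained in all machine-readable outputs; the
  2-significant-figure ratios, 1-significant-figure p-values and
  `mean ± SD` strings exist only in the formatting layer.
- Percent-of-control for amino acids defaults to the ratio of group means
  (`100·\bar{x}_T/\bar{x}_C`), with mean-of-per-sample-ratios available;
  the sources do not state which was used.
- ΔΔCt defaults to efficiency 2.0, reducing exactly to the classic
  $2^{-\Delta\Delta Ct}$; per-gene efficiencies support the
  efficiency-corrected variant. Group tests run on linear fold values
  (matching mean ± SD bar displays), with a log-scale option.
- Cross-model comparison flags between-model ratios beyond a fold
  threshold (default 2, the dashed-line convention) on the disease and
  wild-type sides separately; concordant double-flags classify as
  interspecies (or age-dependent when the compared groups differ by age,
  which requires explicit opt-in — without age metadata that category is
  unreachable), discordant or single-sided flags as model-specific, and
  any ULQ/NQ side as not-comparable. The classification is invariant to
  swapping the two models.
- Degenerate inputs are first-class: identical groups give t = 0, p = 1;
  groups with fewer than two quantified values are "not testable" and
  render as blank p; constant vectors short-circuit the normality check;
  a zero control mean yields an undefined fold ratio marker.

## Problem sizes in the validation suite

The test suite validates stochastic behaviour at sizes chosen to keep the
full run in the low minutes on a single core while leaving Monte-Carlo
noise well inside the asserted bands: 200 replicate datasets for effect
recovery checks (twofold protein change, +25 % amino-acid effect,
fold-3.5 and fold-4 qPCR inductions), 1000 datasets for type-I error
bands, 10^5 replicates for the power-function oracle, and 100-case
property sweeps for the exact oracles (summary vs raw *t*, brute-force
transition means, exhaustive outlier ranking). All seeds are fixed;
every reported number is reproducible from the seed and configuration
alone.

## Known limitations

Single-peptide-per-protein only (multi-peptide protein inference is out
of scope); no peak integration, retention-time alignment or interference
detection; no calibration-curve absolute quantification for amino acids;
no melt-curve QC for qPCR; the outlier screen is a documented stand-alone
method and will not numerically match any specific proprietary
implementation.
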