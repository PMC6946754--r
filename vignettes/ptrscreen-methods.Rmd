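---
title: "From ToF ion counts to screened VOC emitters: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ToF ion counts to screened VOC emitters: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptrscreen)
```

`ptrscreen` turns raw proton-transfer-reaction time-of-flight (PTR-ToF-MS)
ion-count histograms into absolute headspace concentrations and screening
statistics for plant VOC emission experiments, with a synthetic-spectrum
simulator that makes every stage testable without an instrument. This
vignette explains the models behind each stage, the tunable parameters that
matter, and the design choices taken where the problem was genuinely open.

## The measurement model

A ToF spectrum is a histogram `A(i)` of registered ion counts per
flight-time bin, accumulated over `N_ext` extractions (default 30 000 per
second for 30 s, so `N_ext = 9e5`). Three physical layers connect the
histogram to mixing ratios:

1. **ToF law.** Flight time is `t = a*sqrt(m/z) + t0`. The package uses
   this first-order two-parameter law throughout; higher-order corrections
   exist for some analysers but the two-parameter form already reproduces
   sub-mTh accuracy on the simulated instrument, so no third-order term is
   fitted.
2. **Resolution.** Peaks are Gaussian in m/z with constant resolving power
   `m/dm = 7000` (FWHM definition), i.e. `sigma(m) = m / (7000 * 2.3548)`.
   Width is constant in m/dm, not in time, which is how ToF resolution is
   quoted.
3. **Detection.** The detector is non-paralyzable: within one extraction a
   bin can register at most one count, and after a registered count the
   following `d` bins (default `d = 2`) are blind.

## Dead-time correction

With per-extraction Poisson intensity `lambda_i` in bin i, an extraction is
*available* at bin i unless it registered a count in the preceding `d`
bins. Because no extraction can register twice inside a `d`-bin window,
the number of available extractions is exactly

```
N_avail(i) = N_ext - sum_{j=i-d}^{i-1} A(j)
```

and among available extractions the probability of registering nothing is
`exp(-lambda_i)`. Inverting,

```
A'(i) = -N_ext * log(1 - A(i) / N_avail(i))
```

estimates the uncensored expected counts `N_ext * lambda_i`. The `N_ext`
prefactor (rather than `N_avail`) is what makes the correction exact in
expectation under this censoring model: `A(i)/N_avail(i)` estimates the
per-available-extraction registration probability, and the true count rate
applies to all `N_ext` extractions. At `d = 0` the formula reduces to the
familiar Poisson pile-up inversion `-N_ext*log(1 - A/N_ext)`. The package
verifies both the closed form (`-1e6*log(1-1e-4) = 100.005...`) and, by
simulation, that corrected totals are unbiased to better than 1% at rates
where raw counts are tens of percent low.

The simulator implements the same censoring model (binomial thinning with
the exact `N_avail` bookkeeping), so correction-vs-truth tests are genuine
round trips. Counts are drawn by binomial inverse transform on one uniform
per bin, which makes a dead-time run pointwise less than or equal to the
same-seed run without dead time — censoring can only remove counts.

## Internal mass calibration

Each spectrum is calibrated internally against reference ions: by default
the H3(18)O+ primary-ion isotopologue at 21.0221 Th, protonated acetone at
59.0491 Th, and a high-mass calibrant (137.1328 Th) spanning the range.
Each reference is located as the most prominent smoothed maximum within a
±0.3 Th window around its nominal position; a reference whose window shows
no peak-like prominence (6 robust SDs over the local floor) raises an
error naming the ion rather than silently calibrating on noise. Sub-bin
centroids come from an iterated, locally baseline-subtracted Gaussian
centroid. The two-parameter law is then least-squares fitted to the
(centroid, sqrt(m/z)) pairs — exact for two references — and the *achieved
accuracy* is reported as the maximum leave-one-out residual: each
reference is predicted from a fit that excluded it. On simulated 30-s
spectra at realistic count levels this leave-one-out error is well below
1 mTh, which is the accuracy regime that makes sum-formula annotation of
small VOC ions unambiguous.

## Noise reduction, baseline, peak shapes

**Baseline** is a moving low-percentile (10th by default, window 1000
bins) linearly interpolated across the axis and subtracted with clipping
at zero. On integer Poisson counts a low percentile under-sits the mean
floor, so the peak-fit model additionally carries a fitted constant offset
per segment; the baseline step removes slow structure, the offset absorbs
what remains locally.

**Detection** operates on variance-stabilized counts (Anscombe transform
`2*sqrt(x + 3/8)`) smoothed with a Gaussian kernel matched to the expected
local peak width. Stabilization matters: raw Poisson tails at a floor of a
few counts per bin are skewed enough that an "SNR 5" threshold would fire
routinely somewhere among hundreds of thousands of bins. On the
stabilized, smoothed field, a candidate is a local maximum whose
prominence over the local median exceeds `snr` times the local robust
noise (MAD × 1.4826, estimated in 5000-bin windows — wide enough that MAD
estimation error does not inflate the effective threshold). Maxima closer
than half the resolution FWHM are merged (higher wins; ties go to the
lower m/z). The default threshold is SNR 3; detection and targeted
extraction share the same statistic so one threshold has one meaning.

**Peak shape.** The literature fits ToF peaks with "modified Gaussians"
without a canonical closed form; this package uses a Gaussian core plus a
broader co-centered Gaussian wing — the minimal symmetric shape that
captures ToF tailing — with the wing amplitude fraction and width
multiplier as fit parameters, bounded (`0 ≤ wf ≤ 0.5`,
`1.5 ≤ wm ≤ 6`). The shape sits behind `fit_modified_gaussian()` so an
alternative (e.g. exponentially modified Gaussian) could be swapped in
without touching the rest of the chain; fixing the wing fraction to zero
reproduces plain Gaussian least squares exactly, which is tested against
an independent `nls()` fit.

Peaks whose centers lie within 4 expected widths are fitted jointly, and
peaks inside one segment share the width and wing parameters: neighbours a
few mTh apart see the same instrumental shape, and the shared-shape
constraint is what keeps strongly overlapping doublets (1.5 sigma apart)
well conditioned — areas then resolve to a few percent where free-width
joint fits wander by 15% or more. Residuals are Poisson-weighted
(`1/sqrt(counts)`) by default. Non-convergence after two deterministic
restarts falls back to a flagged trapezoidal area within ±2 sigma;
negative fitted amplitudes drop the peak. Areas are computed analytically
from the fitted parameters (`H*sigma*sqrt(2*pi)*(1 + wf*wm)`, divided by
the local bin width and by `N_ext`), making them invariant to the sampling
density of the time axis.

## Kinetic quantification

Standard PTR-MS kinetics: for product-ion intensity `I_R` and primary-ion
intensity `I_H3O+` (counts per extraction, transmission-corrected), the
analyte number density and mixing ratio are

```
[R]  = I_R / (I_H3O+ * k * t_reaction)        (cm^-3)
ppbv = [R] / N_drift * 1e9
```

with `k` the proton-transfer rate coefficient (default `2e-9 cm^3/s`,
per-compound overridable — the "actual" coefficient is compound-specific),
`t_reaction` the ion residence time (~100 µs, configuration), and
`N_drift = p/(kB*T)` the buffer-gas number density. Drift length and
reaction time are instrument geometry, not derivable from panel settings,
so both are explicit configuration with documented typical values (9.3 cm,
100 µs). At the standard screening operating point — 550 V, 2.3 mbar,
110 °C — the derived reduced field is

```{r}
drift_conditions(550, 2.3, 110, drift_length = 9.3)
```

i.e. ~136 Td with the default geometry, inside the 130–150 Td window where
proton-transfer chemistry is clean; `E/N` is always recomputed from the
physical settings, never set directly.

**Primary-ion convention.** The H3O+ peak itself saturates the detector at
realistic source intensities, so quantification measures the rare
H3(18)O+ isotopologue at 21.0221 Th and multiplies by the isotope
abundance ratio (default 487); direct H3O+ mode is available. The
simulator follows the same convention and does not place a peak at
19.018 Th.

Concentrations are normalized by leaf fresh weight (`ppbv/fw_mg`,
exact division); a vial without a usable weight keeps its ppbv values and
is flagged rather than silently dropped. A target ion with no detected
peak is reported as 0 with a below-LOD flag — wild-type reference leaves
show small but genuinely nonzero backgrounds, so zeros are reserved for
true non-detections.

## Screening statistics

* **Welch one-way test** across genotypes, implemented closed-form
  (weights `n_i/s_i^2`, Welch–Satterthwaite denominator df) and verified
  against `stats::oneway.test` to machine precision; two-group calls
  satisfy `F = t^2` against Welch's t-test.
* **Bonferroni** with an explicit family size `m` — by convention the
  number of compounds tested (six in a typical VOC comparison table), not
  the number of pairwise contrasts, matching one adjusted significance
  flag per compound row. Stars use the standard 0.001/0.01/0.05 coding.
* **Compact letter display** from pairwise Welch tests at unadjusted
  alpha = 0.05 (letters encode "do not significantly differ"), via the
  insert-and-absorb algorithm; letters are assigned in ascending-mean
  order so `a` is always the lowest stratum (the wild-type reference in
  practice). The display is a deterministic function of the p-matrix and
  the means.
* **Distribution diagnostics**: median, moment-coefficient skewness
  `g1 = m3/m2^1.5` and excess kurtosis `g2 = m4/m2^2 - 3` (population
  moments, no small-sample correction — the convention is printed in the
  output so alternative conventions are auditable), and Shapiro–Wilk
  normality via Royston's algorithm (`stats::shapiro.test`).
* **Regression with bootstrap band**: closed-form OLS with the slope
  t-test, then case-resampling bootstrap (N = 1999 by default, the value
  conventionally used in this screening protocol) and a pointwise
  percentile 2.5/97.5 band on an x-grid; residual resampling is an
  option. The reported p-value equals the classical slope test exactly;
  the bootstrap supplies the band.
* **Profile correlation**: squared Pearson correlation between two
  equal-length emission profiles with its t-test p. The operation accepts
  any equal-length vectors; published profile comparisons do not always
  state whether the vectors are per-ion emission panels or raw spectral
  points, so the input definition is deliberately the caller's.
* **Ranking and strata**: lines are summarized by the mean over replicate
  vials and ranked with ties broken by line ID; threshold strata (e.g.
  below 10, above 80 ppbv/mgFW) are counted on the same summary. An
  optional per-block normalizer divides analyte values by the block's
  wild-type deviation from the grand wild-type mean — the blocked design
  provides the reference; the arithmetic is a package choice and the raw
  values are always kept alongside.
* **qPCR fold change**: `2^(-ddCt)`.

## The synthetic experiment generator

`simulate_experiment()` emulates the screening study design: 116
independent transgenic lines, autosampler blocks of 32 vials with one
wild-type (Col-0) reference each (lines fill blocks sequentially;
measurement order is randomized across the run and stored), one leaf per
vial with fresh weight ~ N(20, 3) mg.

* **Emissions** across lines are log-normal with median 5 ppbv/mgFW and
  `sdlog = 0.512`, giving population skewness ≈ 1.8 — the strong
  right-skew regime reported for transgene positional effects. (Observed
  screens can be more extreme — e.g. a handful of lines above
  80 ppbv/mgFW alongside a median near 5 — which corresponds to a heavier
  tail than this parameterization; the skewness-matched log-normal is the
  documented default and all parameters are exposed.)
* **Expression** (qPCR fold change) is linear in true emission plus
  Gaussian noise sized from the realized top-29 emission variance so that
  the squared correlation among the top 29 emitters is 0.28 in the
  population — reproducing the "expression is a weak proxy for emission"
  regime. Wild-type expression is background.
* **Spectra** carry the analyte ion (protonated isoprene, C5H9+), two
  calibrant ions at constant mixing ratios, the primary-ion isotopologue,
  and Poisson baseline (2e-6 counts/bin/extraction), all through the same
  kinetic forward model that quantification inverts, with dead-time
  censoring as above. Col-0 vials get a 0.14 ppbv/mgFW isoprene
  background.

What the generator does **not** emulate: instrument drift over a
multi-hour run (each spectrum is calibrated independently, as 30-s
measurements justify), fragmentation chemistry (fragment ions are
specified directly as sources), humidity-dependent primary-ion cluster
chemistry, mass-dependent transmission curves (flat by default), and
chromatographic or memory effects between vials. Passing tests therefore
demonstrate correctness of the processing chain under the stated
statistical model of the instrument, not robustness to every artifact of
real hardware.

## Numerical and scale choices

Tests and the acceptance script run the full chain at reduced but
representative sizes chosen for a single-CPU desktop run: the blind
screening check processes one full 116-line experiment (120 vials at full
bin density), the dead-time Monte-Carlo uses 40–60 replicate spectra on a
narrowed mass window, calibration accuracy uses 8–50 spectra, Welch size
uses 10 000 null replicates, and bootstrap coverage uses 150 seeds at
N = 1999. Deterministic seeds are set at every entry point; the simulator
is bit-reproducible from its seed.

Degenerate inputs are contracts, not crashes: saturation (counts reaching
available extractions) names the bin; a missing calibrant names the ion;
zero-variance groups, constant predictors and zero-variance profiles are
rejected; constant vectors make Shapiro–Wilk undefined and are flagged.
Sum-formula annotation breaks ties by fewer heteroatoms then Hill string;
duplicate-maximum merges keep the lower m/z; no ring/double-bond filter is
applied by default (an optional RDBE ≥ 0 filter exists).

## Storage

Spectra are exchanged as a run directory: a JSON manifest (schema version,
instrument parameters, per-spectrum metadata) plus one sparse
`bin,count` CSV per spectrum — a lossless, self-describing plain-text
round trip. Calibrations serialize to JSON; all tabular outputs are CSV.
Every pipeline run logs an MD5 hash of its full configuration alongside
the seed.

## Known limitations

* Isobaric compounds (e.g. monoterpene isomers) are not deconvolved —
  they are indistinguishable at this resolution by construction; the
  annotation reports the sum formula only.
* Concentrations assume the default rate coefficient unless a
  compound-specific `k` is configured; absolute accuracy is bounded by
  how well `k` and the reaction time are known.
* The Welch/letter machinery needs replicated genotypes (n ≥ 2 per
  group); single-vial-per-line designs support ranking and distribution
  diagnostics, not per-line inference.
* Below-LOD zeros bias group means of very low emitters slightly
  downward; flags are carried so users can filter.
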