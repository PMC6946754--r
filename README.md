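# ptrscreen

High-throughput screening of plant volatile organic compound (VOC)
emissions by PTR-ToF-MS, as an R package: from raw time-of-flight
ion-count histograms to absolute headspace concentrations (ppbv, normalized
per mg leaf fresh weight) to the statistics used to rank transgenic lines
by emission. A built-in synthetic-spectrum simulator emulates the
instrument and a whole randomized-block screening experiment, so the entire
chain is testable and reproducible without instrument data.

Intended users: groups running direct-injection PTR-ToF-MS headspace
screens of many genotypes (e.g. transgenic *Arabidopsis* lines expressing a
candidate VOC biosynthetic gene such as an isoprene synthase) who need a
transparent, scriptable processing and statistics pipeline.

## The processing chain

1. **Dead-time correction** (`correct_dead_time`). A non-paralyzable
   detector registers at most one count per bin per extraction and is blind
   for `d` bins after a count. With `N_avail(i) = N_ext − Σ A(i−d..i−1)`,
   the Poisson-statistics correction

   `A′(i) = −N_ext · ln(1 − A(i)/N_avail(i))`

   is exact in expectation under that censoring model and reduces to the
   pile-up inversion `−N_ext·ln(1 − A/N_ext)` at `d = 0`.
2. **Internal mass calibration** (`calibrate`). First-order ToF law
   `t = a√(m/z) + t0`, least-squares fitted to reference-ion centroids
   (defaults: H3¹⁸O⁺ 21.0221 Th, protonated acetone 59.0491 Th, 137.1328
   Th); achieved accuracy reported as the max leave-one-out residual —
   sub-mTh at realistic 30-s count levels.
3. **Peak extraction** (`detect_peaks`, `fit_modified_gaussian`,
   `integrate_table`). Baseline removal (moving 10th percentile),
   variance-stabilized matched-filter detection, and modified-Gaussian
   fitting (Gaussian core + co-centered broader wing; overlapping peaks
   fitted jointly with shared shape), with analytic per-extraction areas.
4. **Sum-formula annotation** (`annotate_mz`, `monoisotopic_mz`).
   Exhaustive bounded enumeration over C/H/O/N with deterministic ranking;
   monoisotopic cation masses include the electron mass
   (C5H9O⁺ → 85.0648 Th).
5. **Kinetic quantification** (`concentration_ppbv`, `compute_E_over_N`,
   `build_emission_table`). Standard PTR kinetics
   `[R] = I_R/(I_{H3O+}·k·t)`, mixing ratio `[R]/N_drift·10⁹` ppbv,
   H3O⁺ measured via its ¹⁸O isotopologue × 487; E/N derived from
   550 V / 2.3 mbar / 110 °C / 9.3 cm ≈ 136 Td; fresh-weight
   normalization to ppbv·mgFW⁻¹.
6. **Screening statistics** (`welch_anova`, `letter_groups`, `bonferroni`,
   `distribution_summary`, `ols_bootstrap`, `profile_correlation`,
   `select_lines`, `fold_change`). Welch one-way tests with
   Bonferroni-corrected stars and compact letter displays, distribution
   diagnostics (median, g1 skewness, g2 excess kurtosis, Shapiro–Wilk),
   OLS with case-resampling bootstrap bands (N = 1999), emission-profile
   correlations, line ranking/strata, ΔΔCt fold changes.
7. **Simulation** (`simulate_spectrum`, `simulate_experiment`,
   `synthetic_panel`). Inverts the forward model: kinetics → count rates →
   Gaussian peaks on the ToF axis → Poisson baseline → dead-time
   censoring; whole experiments with blocked design, log-normal
   right-skewed emissions, and expression only weakly correlated
   (R² ≈ 0.28) with emission.

## Worked example

Simulate a small blocked screen, process it blind, and rank the lines:

```r
library(ptrscreen)

design <- experiment_design(n_lines = 12, block_size = 8, seed = 42)
sim <- simulate_experiment(design)

res <- process_experiment(sim$spectra, sim$samples, "C5H9+",
                          quant_params(), drift_conditions())
head(subset(as.data.frame(res$emissions), ion == "C5H9+",
            select = c(vial, line, genotype, fw_mg, ppbv, ppbv_per_mg)), 5)
#>   vial line   genotype    fw_mg      ppbv ppbv_per_mg
#> 1 V001 L001 transgenic 25.68558 260.14556   10.128078
#> 2 V002 L002 transgenic 18.70859  71.09983    3.800384
#> 3 V003 L003 transgenic 19.22819 115.16694    5.989483
#> 4 V004 L004 transgenic 14.71051 101.80448    6.920527
#> 5 V005 L005 transgenic 21.38029 131.59292    6.154870
```

Each row is one vial: the headspace isoprene (C5H9⁺) concentration in
ppbv recovered from the spectrum, and the same value normalized by that
leaf's fresh weight. Ranking, strata and distribution diagnostics:

```r
sel <- select_lines(res$emissions, ion = "C5H9+",
                    thresholds = c(-10, 80), top_k = 3)
sel$ranking[1:3, ]
#>   line emission rank
#> 1 L012 16.21897    1
#> 2 L009 14.32110    2
#> 3 L007 10.87015    3
sel$strata
#>   label n
#> 1  < 10 8
#> 2  > 80 0

ds <- distribution_summary(sel$ranking$emission)
#> median 6.54, skewness 0.77, excess kurtosis -0.64, Shapiro-Wilk p = 0.101
```

Eight of the twelve lines emit below 10 ppbv·mgFW⁻¹ — the right-skewed
shape typical of independent transformation events. Regressing recovered
emission on the (simulated) transgene expression with a bootstrap band:

```r
tr <- merge(sel$ranking, sim$truth, by = "line")
ols_bootstrap(tr$fold_change, tr$emission, seed = 1)
#> <ols_bootstrap> y = 5.973 + 0.3295 x, R^2 = 0.3516, p = 0.0422
#>   (n = 12, case resampling, N = 1999)
```

A command-line runner wrapping the same functions ships in
`inst/cli/ptrscreen`:

```sh
Rscript inst/cli/ptrscreen all --seed 1 --out-dir run1
```

writes the spectrum container, emission tables (long + wide CSV),
per-vial calibration JSONs, and the screening/ranking tables, logging the
configuration hash and seed.

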