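# Baseline removal, detection, modified-Gaussian fitting.

test_that("baseline removal is exact for flat and empty spectra", {
  flat <- rep(7.5, 5000)
  out <- remove_baseline(flat, 500)
  expect_true(all(abs(out$signal) < 1e-9))
  expect_true(all(abs(out$baseline - 7.5) < 1e-9))

  zero <- numeric(3000)
  out0 <- remove_baseline(zero, 500)
  expect_identical(out0$signal, zero)

  expect_error(remove_baseline(zero, 2), "at least 3")
  expect_error(remove_baseline(numeric(10), 100), "larger than")
})

test_that("a peak on a constant pedestal is recovered within 2%", {
  p <- narrow_params(baseline_rate = 0, dead_time_bins = 0)
  cal <- calibration_model(p$calib_a, p$calib_t0)
  # deterministic Gaussian peak + constant pedestal of 50 counts
  m0 <- 69.0699; sig <- peak_sigma_mz(m0, p$resolution)
  bins <- seq_len(p$n_bins)
  mz <- ((bins - p$calib_t0) / p$calib_a)^2
  height <- 4000
  counts <- 50 + height * exp(-(mz - m0)^2 / (2 * sig^2))
  out <- remove_baseline(counts, 1000)
  pk <- fit_modified_gaussian(out$signal, cal,
                              round(bin_of_mz(cal, m0)), p,
                              n_extractions = 1)
  true_area <- height * sig * sqrt(2 * pi) / (2 * sqrt(m0) / p$calib_a)
  expect_equal(pk$area_per_extraction, true_area, tolerance = 0.02)
  expect_equal(pk$mz, m0, tolerance = 1e-4)
})

test_that("two ions one Th apart are both detected at m/dm 7000", {
  p <- narrow_params()
  set.seed(5)
  sp <- simulate_spectrum(list(ion_source(69.0699, count_rate = 5000),
                               ion_source(70.0699, count_rate = 5000)), p)
  cal <- calibrate(sp, reference_mz = c(21.0221, 69.0699))
  bl <- remove_baseline(correct_dead_time(sp), 1000)
  det <- detect_peaks(bl$signal, cal, p, snr = 5)
  hits <- det$mz[det$mz > 68 & det$mz < 71]
  expect_equal(length(hits), 2L)
  expect_equal(sort(hits), c(69.0699, 70.0699), tolerance = 1e-4)
})

test_that("baseline-only spectra rarely produce detections at snr 5", {
  p <- narrow_params()
  cal <- calibration_model(p$calib_a, p$calib_t0)
  nseed <- 25
  clean <- 0
  for (s in seq_len(nseed)) {
    set.seed(700 + s)
    sp <- simulate_spectrum(list(), p, include_primary = FALSE)
    bl <- remove_baseline(correct_dead_time(sp), 1000)
    clean <- clean + (nrow(detect_peaks(bl$signal, cal, p, snr = 5)) == 0L)
  }
  expect_gte(clean / nseed, 0.88)
})

test_that("a pure Gaussian peak is fitted with vanishing wing fraction", {
  p <- narrow_params(baseline_rate = 0, dead_time_bins = 0)
  cal <- calibration_model(p$calib_a, p$calib_t0)
  m0 <- 59.0491; sig <- peak_sigma_mz(m0, p$resolution)
  bins <- seq_len(p$n_bins)
  mz <- ((bins - p$calib_t0) / p$calib_a)^2
  counts <- 1e4 * exp(-(mz - m0)^2 / (2 * sig^2))
  pk <- fit_modified_gaussian(counts, cal, round(bin_of_mz(cal, m0)), p,
                              n_extractions = 1)
  expect_equal(pk$mz, m0, tolerance = 1e-6)
  expect_equal(pk$sigma, sig, tolerance = 1e-4)
  expect_lt(pk$wing_frac, 1e-3)
  true_area <- 1e4 * sig * sqrt(2 * pi) / (2 * sqrt(m0) / p$calib_a)
  expect_equal(pk$area_per_extraction, true_area, tolerance = 1e-3)
})

test_that("wing-free fitting equals plain Gaussian least squares", {
  p <- narrow_params(baseline_rate = 0, dead_time_bins = 0)
  cal <- calibration_model(p$calib_a, p$calib_t0)
  m0 <- 45.03; sig <- peak_sigma_mz(m0, p$resolution)
  bins <- seq_len(p$n_bins)
  mz <- ((bins - p$calib_t0) / p$calib_a)^2
  set.seed(77)
  counts <- pmax(5000 * exp(-(mz - m0)^2 / (2 * sig^2)) +
                   rnorm(p$n_bins, 0, 5), 0)
  pk <- fit_modified_gaussian(counts, cal, round(bin_of_mz(cal, m0)), p,
                              n_extractions = 1, fit_wings = FALSE,
                              weighting = "none")
  expect_equal(pk$wing_frac, 0)
  # independent plain-Gaussian fit via nls on the same window
  win <- abs(mz - m0) < 6 * sig
  df <- data.frame(x = mz[win], y = counts[win])
  ref <- nls(y ~ off + h * exp(-(x - c0)^2 / (2 * s^2)), df,
             start = list(off = 0, h = max(df$y), c0 = m0, s = sig))
  cf <- coef(ref)
  expect_equal(pk$mz, unname(cf["c0"]), tolerance = 1e-6)
  expect_equal(pk$sigma, unname(cf["s"]), tolerance = 1e-3)
})

test_that("overlapping peaks 1.5 sigma apart are resolved within 5%", {
  p <- narrow_params(baseline_rate = 0, dead_time_bins = 0)
  cal <- calibration_model(p$calib_a, p$calib_t0)
  m0 <- 69.0699; sig <- peak_sigma_mz(m0, p$resolution)
  m1 <- m0 + 1.5 * sig
  bins <- seq_len(p$n_bins)
  mz <- ((bins - p$calib_t0) / p$calib_a)^2
  dmz <- 2 * sqrt(m0) / p$calib_a
  errs <- matrix(NA_real_, 10, 2)
  for (s in seq_len(10)) {
    set.seed(800 + s)
    lam <- 2e4 * exp(-(mz - m0)^2 / (2 * sig^2)) +
      1.2e4 * exp(-(mz - m1)^2 / (2 * sig^2))
    counts <- rpois(p$n_bins, lam)
    pk <- fit_modified_gaussian(counts, cal,
                                round(bin_of_mz(cal, c(m0, m1))), p,
                                n_extractions = 1, fit_wings = FALSE)
    expect_equal(nrow(pk), 2L)
    a_true <- c(2e4, 1.2e4) * sig * sqrt(2 * pi) / dmz
    errs[s, ] <- (pk$area_per_extraction - a_true) / a_true
  }
  expect_true(all(abs(errs) < 0.05))
})

test_that("fitted area is stable under doubled sampling density", {
  area_at <- function(a_cal) {
    p <- instrument_params(calib_a = a_cal, calib_t0 = 5000,
                           mz_range = c(15, 80), baseline_rate = 0,
                           dead_time_bins = 0)
    cal <- calibration_model(p$calib_a, p$calib_t0)
    m0 <- 69.0699; sig <- peak_sigma_mz(m0, p$resolution)
    bins <- seq_len(p$n_bins)
    mz <- ((bins - p$calib_t0) / p$calib_a)^2
    counts <- 1e4 * exp(-(mz - m0)^2 / (2 * sig^2))
    pk <- fit_modified_gaussian(counts, cal, round(bin_of_mz(cal, m0)), p,
                                n_extractions = 1)
    # per-extraction area times local bin width: density-independent
    pk$area_per_extraction * 2 * sqrt(m0) / p$calib_a
  }
  expect_equal(area_at(42000), area_at(21000), tolerance = 0.01)
})

test_that("integrate_table composes the chain and annotates known ions", {
  p <- narrow_params()
  set.seed(41)
  sp <- simulate_spectrum(list(ion_source("C5H9+", ppbv = 300),
                               ion_source("C3H7O+", ppbv = 20)), p,
                          vial_id = "VX")
  cal <- calibrate(sp, reference_mz = c(21.0221, 59.0491, 69.0699))
  tab <- integrate_table(sp, cal, snr = 5)
  expect_s3_class(tab, "peak_table")
  expect_true(!is.unsorted(tab$mz))
  expect_true("C5H9+" %in% tab$formula)
  expect_true("C3H7O+" %in% tab$formula)
  expect_false(is.na(attr(tab, "primary_intensity")))
  # total fitted area bounded by total signal in the region (+ tolerance)
  bl <- remove_baseline(correct_dead_time(sp), 1000)
  reg <- round(bin_of_mz(cal, 69.07 - 0.1)):round(bin_of_mz(cal, 69.07 + 0.1))
  tot_sig <- sum(bl$signal[reg]) / sp$n_extractions
  fitted <- sum(tab$area_per_extraction[abs(tab$mz - 69.07) < 0.1])
  expect_lte(fitted, tot_sig * 1.05)
})

test_that("an empty spectrum yields an empty peak table", {
  p <- narrow_params(baseline_rate = 0)
  sp <- simulate_spectrum(list(), p, include_primary = FALSE, seed = 2)
  cal <- calibration_model(p$calib_a, p$calib_t0)
  tab <- integrate_table(sp, cal)
  expect_identical(nrow(tab), 0L)
})

test_that("targeted extraction flags absent ions as below LOD", {
  p <- narrow_params()
  set.seed(43)
  sp <- simulate_spectrum(list(ion_source("C5H9+", ppbv = 300)), p,
                          vial_id = "VY")
  cal <- calibrate(sp, reference_mz = c(21.0221, 69.0699))
  tab <- extract_targets(sp, c("C5H9+", "C7H11+"), calibration = cal)
  expect_true("C5H9+" %in% tab$formula)
  expect_false("C7H11+" %in% tab$formula)  # not simulated: below LOD
  expect_gt(attr(tab, "primary_intensity"), 0)
})
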