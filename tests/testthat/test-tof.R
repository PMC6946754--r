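# Dead-time correction and internal mass calibration.

test_that("dead-time correction reproduces the closed-form pile-up inversion", {
  s <- raw_spectrum(c(0L, 100L, 0L), n_extractions = 1e6, dead_time_bins = 0)
  out <- correct_dead_time(s)
  expect_equal(out[2], -1e6 * log(1 - 1e-4), tolerance = 1e-12)
  expect_equal(out[2], 100.0050003, tolerance = 1e-7)
  expect_identical(out[c(1, 3)], c(0, 0))
})

test_that("correction is zero on empty spectra and never decreases counts", {
  s <- raw_spectrum(integer(100), n_extractions = 1e5)
  expect_identical(correct_dead_time(s), structure(rep(0, 100),
                   n_avail = rep(1e5, 100)))
  set.seed(1)
  a <- rpois(200, 50)
  s2 <- raw_spectrum(a, n_extractions = 1e4, dead_time_bins = 3)
  out <- correct_dead_time(s2)
  expect_true(all(out >= a))
  # monotone in A(i): raising one bin raises its corrected value
  a2 <- a; a2[50] <- a2[50] + 10
  out2 <- correct_dead_time(raw_spectrum(a2, 1e4, dead_time_bins = 3))
  expect_gt(out2[50], out[50])
})

test_that("available extractions shrink by the preceding d-bin window", {
  a <- c(1000L, 2000L, 500L, 0L)
  s <- raw_spectrum(a, n_extractions = 1e4, dead_time_bins = 2)
  out <- correct_dead_time(s)
  n_avail <- attr(out, "n_avail")
  expect_equal(n_avail, c(1e4, 1e4 - 1000, 1e4 - 3000, 1e4 - 2500))
  expect_equal(out[2], -1e4 * log(1 - 2000 / 9000), tolerance = 1e-12)
})

test_that("saturation and invalid metadata raise identifying errors", {
  expect_error(correct_dead_time(
    raw_spectrum(c(0L, 900L, 200L), n_extractions = 1000,
                 dead_time_bins = 1)), "saturation.*bin")
  expect_error(raw_spectrum(c(1L), n_extractions = 0), "positive")
  expect_error(raw_spectrum(c(5L), n_extractions = 2), "exceed")
})

test_that("corrected counts are unbiased where raw counts are biased low", {
  p <- narrow_params(dead_time_bins = 2, baseline_rate = 0)
  ion <- ion_source(69.0699, count_rate = 3e5)
  nrep <- 60
  set.seed(11)
  raw_ratio <- cor_ratio <- numeric(nrep)
  for (r in seq_len(nrep)) {
    sp <- simulate_spectrum(list(ion), p, include_primary = FALSE)
    lt <- attr(sp, "lambda_total")
    sel <- which(lt > 0)
    raw_ratio[r] <- sum(sp$counts[sel]) / sum(lt[sel])
    cor_ratio[r] <- sum(correct_dead_time(sp)[sel]) / sum(lt[sel])
  }
  expect_lt(mean(raw_ratio), 0.95)        # raw biased low by >= 5%
  expect_lt(abs(mean(cor_ratio) - 1), 0.01)  # corrected within 1% of truth
})

test_that("ToF law axis is exact, monotone and invertible", {
  m <- calibration_model(a = 8000, t0 = 1200)
  expect_equal(mz_axis(m, 1200 + 8000), 1)
  expect_equal(mz_axis(m, 1200 + 8000 * sqrt(69.0699)), 69.0699,
               tolerance = 1e-12)
  expect_equal(mz_axis(m, bin_of_mz(m, 137.1328)), 137.1328,
               tolerance = 1e-12)
  bins <- seq(1300, 1e5, length.out = 50)
  expect_true(all(diff(mz_axis(m, bins)) > 0))
  expect_error(mz_axis(m, 1100), "pre-pulse")
})

test_that("calibration inverts a noiseless spectrum essentially exactly", {
  p <- instrument_params(calib_a = 8000, calib_t0 = 1200,
                         mz_range = c(15, 160), baseline_rate = 0,
                         dead_time_bins = 0)
  refs <- c(21.0221, 59.0491, 137.1328)
  counts <- numeric(p$n_bins)
  for (m in refs) {                     # deterministic Gaussian profiles
    sig <- peak_sigma_mz(m, p$resolution)
    bins <- floor(8000 * sqrt(m - 6 * sig) + 1200):
      ceiling(8000 * sqrt(m + 6 * sig) + 1200)
    mi <- ((bins - 1200) / 8000)^2
    counts[bins] <- counts[bins] +
      round(1e6 * dnorm(mi, m, sig) / dnorm(0, 0, sig))
  }
  sp <- raw_spectrum(as.integer(counts), n_extractions = 1e9,
                     dead_time_bins = 0, params = p)
  cal <- calibrate(sp, reference_mz = refs)
  expect_equal(cal$a, 8000, tolerance = 1e-6)
  expect_lt(abs(cal$t0 - 1200), 0.01)
  expect_lte(cal$achieved_accuracy, 1e-4)
})

test_that("calibration reaches sub-mTh accuracy on realistic noisy spectra", {
  p <- instrument_params(calib_a = 8000, calib_t0 = 1200,
                         mz_range = c(15, 160), baseline_rate = 0)
  set.seed(21)
  refs <- c(21.0221, 59.0491, 137.1328)
  sp <- simulate_spectrum(list(ion_source(59.0491, count_rate = 2e5),
                               ion_source(137.1328, count_rate = 2e5)),
                          p, quant = quant_params(primary_count_rate = 5e7))
  cal <- calibrate(sp, reference_mz = refs)
  expect_equal(cal$a, 8000, tolerance = 1e-5)
  expect_lte(cal$achieved_accuracy, 0.001)
})

test_that("calibration errors name missing or degenerate references", {
  p <- narrow_params()
  set.seed(3)
  sp <- simulate_spectrum(list(), p)  # only the primary isotopologue
  expect_error(calibrate(sp, reference_mz = c(21.0221, 59.0491)),
               "59.0491.*not found|not found.*59")
  expect_error(calibrate(sp, reference_mz = c(21.0221, 21.0221)),
               "degenerate")
  expect_error(calibrate(sp, reference_mz = 21.0221), "at least 2")
})

test_that("calibration models serialize to JSON and back", {
  m <- calibration_model(8000.5, 1200.25,
                         references = data.frame(label = "a", mz = 21.0221,
                                                 centroid_bin = 37893.2),
                         achieved_accuracy = 4.2e-4)
  path <- tempfile(fileext = ".json")
  write_calibration(m, path)
  m2 <- read_calibration(path)
  expect_equal(m2$a, m$a)
  expect_equal(m2$t0, m$t0)
  expect_equal(m2$achieved_accuracy, m$achieved_accuracy)
})
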