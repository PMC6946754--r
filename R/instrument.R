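# Instrument parameterization and the time-of-flight law.

#' Instrument parameters
#'
#' Describes the ToF analyser and acquisition settings used both by the
#' simulator (forward model) and by spectrum processing (nominal calibration,
#' dead-time window).
#'
#' @param calib_a nominal ToF-law slope, bins per sqrt(Th). Together with
#'   `calib_t0` this fixes the nominal mapping `t = a*sqrt(m/z) + t0`.
#' @param calib_t0 nominal ToF-law offset, bins.
#' @param resolution mass resolving power m/dm (FWHM definition); 7000 for
#'   the ToF analysers used in high-throughput VOC screening.
#' @param mz_range numeric length-2, acquired m/z window in Th.
#' @param n_bins number of ToF histogram bins; defaults to just covering
#'   `mz_range` under the nominal calibration.
#' @param dead_time_bins detector dead time d, in bins: after a registered
#'   count the following d bins of the same extraction cannot register
#'   (non-paralyzable model).
#' @param extraction_rate ToF extractions per second.
#' @param baseline_rate mean baseline (dark + chemical) counts per bin per
#'   extraction.
#' @return An object of class `instrument_params`.
#' @export
instrument_params <- function(calib_a = 21000, calib_t0 = 5000,
                              resolution = 7000, mz_range = c(15, 300),
                              n_bins = NULL, dead_time_bins = 2,
                              extraction_rate = 30000,
                              baseline_rate = 2e-6) {
  stopifnot(calib_a > 0, resolution > 0, dead_time_bins >= 0,
            length(mz_range) == 2L, mz_range[1] < mz_range[2],
            mz_range[1] > 0, extraction_rate > 0, baseline_rate >= 0)
  if (is.null(n_bins))
    n_bins <- ceiling(calib_t0 + calib_a * sqrt(mz_range[2] + 1))
  stopifnot(n_bins > calib_t0 + calib_a * sqrt(mz_range[2]))
  structure(list(calib_a = calib_a, calib_t0 = calib_t0,
                 resolution = resolution, mz_range = mz_range,
                 n_bins = as.integer(n_bins),
                 dead_time_bins = as.integer(dead_time_bins),
                 extraction_rate = extraction_rate,
                 baseline_rate = baseline_rate),
            class = "instrument_params")
}

#' @export
print.instrument_params <- function(x, ...) {
  cat("<instrument_params>\n")
  cat(sprintf("  ToF law: t = %.6g*sqrt(m) + %.6g (bins), %d bins\n",
              x$calib_a, x$calib_t0, x$n_bins))
  cat(sprintf("  m/dm = %g, m/z %g-%g Th, dead time %d bins\n",
              x$resolution, x$mz_range[1], x$mz_range[2], x$dead_time_bins))
  cat(sprintf("  %g extractions/s, baseline %g counts/bin/extraction\n",
              x$extraction_rate, x$baseline_rate))
  invisible(x)
}

# First-order ToF law: flight-time bin as a function of m/z and back.
tof_bin_of_mz <- function(mz, a, t0) a * sqrt(mz) + t0

tof_mz_of_bin <- function(bin, a, t0) {
  if (any(bin <= t0))
    stop("bin(s) at or before t0: pre-pulse region has no m/z")
  ((bin - t0) / a)^2
}

# Gaussian kernel smoothing with edge passthrough.
gauss_smooth <- function(x, sigma_bins) {
  half <- ceiling(3 * sigma_bins)
  w <- stats::dnorm(-half:half, 0, sigma_bins)
  w <- w / sum(w)
  out <- stats::filter(x, w, sides = 2)
  na <- is.na(out)
  out[na] <- x[na]
  as.numeric(out)
}

#' Gaussian peak width (sigma, Th) at a given m/z for a resolution m/dm
#'
#' The resolving power is quoted on FWHM, so sigma = m / (resolution *
#' 2*sqrt(2*log(2))).
#' @param mz m/z in Th.
#' @param resolution resolving power m/dm.
#' @return sigma in Th.
#' @export
peak_sigma_mz <- function(mz, resolution) mz / (resolution * 2 * sqrt(2 * log(2)))
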