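# Raw spectra, Poisson dead-time correction, internal mass calibration.

#' Construct a raw ToF spectrum
#'
#' The pipeline's input unit: one vial's histogram of registered ion counts
#' per flight-time bin, accumulated over all ToF extractions of a (typically
#' 30 s) measurement, plus the acquisition metadata needed to undo detector
#' dead-time losses.
#'
#' @param counts integer vector of registered counts per bin.
#' @param n_extractions number of ToF extractions N_ext accumulated.
#' @param dead_time_bins detector dead time in bins (non-paralyzable).
#' @param duration measurement duration in seconds.
#' @param vial_id identifier of the measured vial.
#' @param params optional [instrument_params()] to carry along.
#' @return Object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(counts, n_extractions, dead_time_bins = 2,
                         duration = 30, vial_id = NA_character_,
                         params = NULL) {
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative integers")
  if (n_extractions <= 0) stop("n_extractions must be positive")
  if (any(counts > n_extractions))
    stop("counts exceed n_extractions in bin(s) ",
         paste(utils::head(which(counts > n_extractions), 3), collapse = ", "))
  structure(list(counts = counts, n_extractions = n_extractions,
                 dead_time_bins = as.integer(dead_time_bins),
                 duration = duration, vial_id = vial_id, params = params),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> vial %s: %d bins, %.3g extractions, %g s, %d total counts\n",
              x$vial_id, length(x$counts), x$n_extractions, x$duration,
              sum(x$counts)))
  invisible(x)
}

#' Poisson-statistics dead-time correction
#'
#' After a registered count, a non-paralyzable detector is blind for the next
#' d bins of the same extraction, so high count rates are biased low. With
#' N_ext extractions and registered counts A(i), the number of extractions
#' still available at bin i is
#' `N_avail(i) = N_ext - sum(A[(i-d):(i-1)])` (each blocked extraction
#' registered exactly one count in the preceding window). Among available
#' extractions the probability of registering nothing is `exp(-lambda_i)`
#' for true per-extraction Poisson mean `lambda_i`, giving the estimate
#'
#'   `A'(i) = -N_ext * log(1 - A(i) / N_avail(i))`
#'
#' which is exact in expectation under this censoring model and reduces to
#' the pure Poisson pile-up inversion `-N_ext*log(1 - A/N_ext)` at d = 0.
#'
#' @param spectrum a [raw_spectrum()].
#' @return Numeric vector of corrected (real-valued) counts per bin, with
#'   the per-bin `N_avail` attached as attribute `"n_avail"`. Corrected
#'   counts are never below the registered counts.
#' @examples
#' s <- raw_spectrum(c(0L, 100L, 0L), n_extractions = 1e6, dead_time_bins = 0)
#' correct_dead_time(s)[2]  # -1e6*log(1 - 1e-4) = 100.005...
#' @export
correct_dead_time <- function(spectrum) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  a <- spectrum$counts
  n_ext <- spectrum$n_extractions
  d <- spectrum$dead_time_bins
  n <- length(a)
  if (d > 0 && n > 0) {
    cs <- cumsum(as.numeric(a))
    i <- seq_len(n)
    lo <- pmax(i - d - 1L, 0L)
    hi <- i - 1L
    win <- ifelse(hi >= 1L, cs[pmax(hi, 1L)], 0) - ifelse(lo >= 1L, cs[pmax(lo, 1L)], 0)
    win[hi < 1L] <- 0
    n_avail <- n_ext - win
  } else {
    n_avail <- rep.int(n_ext, n)
  }
  sat <- which(a >= n_avail & a > 0)
  if (length(sat))
    stop("detector saturation: registered counts reach available extractions in bin(s) ",
         paste(utils::head(sat, 5), collapse = ", "))
  out <- -n_ext * log1p(-a / n_avail)
  out[a == 0] <- 0
  attr(out, "n_avail") <- n_avail
  out
}

#' Calibration model for the flight-time axis
#'
#' Parameters of the first-order ToF law `t = a*sqrt(m/z) + t0` fitted to
#' reference ions found inside a spectrum, plus the leave-one-out mass
#' accuracy actually achieved.
#'
#' @param a fitted slope, bins per sqrt(Th); must be positive.
#' @param t0 fitted offset, bins.
#' @param references data.frame of the matched reference ions
#'   (`label`, `mz`, `centroid_bin`).
#' @param achieved_accuracy maximum absolute leave-one-out m/z residual, Th
#'   (`NA` when fewer than 3 references make it undefined).
#' @return Object of class `calibration_model`.
#' @export
calibration_model <- function(a, t0, references = NULL,
                              achieved_accuracy = NA_real_) {
  stopifnot(is.numeric(a), a > 0, is.numeric(t0))
  structure(list(a = a, t0 = t0, references = references,
                 achieved_accuracy = achieved_accuracy),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> t = %.6g*sqrt(m) + %.6g bins", x$a, x$t0))
  if (!is.na(x$achieved_accuracy))
    cat(sprintf("; LOO accuracy %.2g mTh", 1000 * x$achieved_accuracy))
  cat("\n")
  invisible(x)
}

# Gaussian-weighted centroid (in bin units) of a peak near `guess_bin`.
# Iterates window re-centering; subtracts the local baseline estimated from
# the window edges so wings/offset do not bias the centroid.
peak_centroid_bin <- function(counts, guess_bin, halfwidth_bins,
                              n_iter = 3L) {
  n <- length(counts)
  center <- guess_bin
  for (it in seq_len(n_iter)) {
    lo <- max(1L, floor(center - halfwidth_bins))
    hi <- min(n, ceiling(center + halfwidth_bins))
    seg <- counts[lo:hi]
    edge <- c(utils::head(seg, 3), utils::tail(seg, 3))
    y <- pmax(seg - stats::median(edge), 0)
    tot <- sum(y)
    if (tot <= 0) return(NA_real_)
    center <- sum((lo:hi) * y) / tot
  }
  center
}

#' Internal mass calibration of a ToF spectrum
#'
#' Locates each reference ion as the highest local maximum within a search
#' window around its nominal position, estimates sub-bin peak centroids, and
#' least-squares fits the ToF law `t = a*sqrt(m/z) + t0`. With exactly two
#' references the fit is exact; with three or more, the achieved mass
#' accuracy is computed by leave-one-out refitting (each reference predicted
#' from a model fitted without it).
#'
#' @param spectrum a [raw_spectrum()]; dead-time-corrected counts are used
#'   when available, otherwise the correction is applied internally.
#' @param reference_mz numeric vector (length >= 2) of theoretical reference
#'   m/z values, or a character vector of formula strings; the default set is
#'   the H3(18O)+ primary-ion isotopologue plus protonated acetone and a
#'   high-mass calibrant spanning the acquired range.
#' @param search_window half-width of the search window in Th (default 0.3).
#' @param params [instrument_params()] supplying the nominal axis; taken
#'   from the spectrum when `NULL`.
#' @param min_counts minimum summed counts a reference peak must carry to be
#'   considered found (default 20).
#' @return A [calibration_model()].
#' @export
calibrate <- function(spectrum, reference_mz = NULL, search_window = 0.3,
                      params = NULL, min_counts = 20) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  params <- params %||% spectrum$params
  if (is.null(params))
    stop("instrument params needed for the nominal search axis")
  if (is.null(reference_mz))
    reference_mz <- default_reference_mz()
  labels <- if (is.character(reference_mz)) reference_mz
            else sprintf("%.4f", reference_mz)
  mz <- if (is.character(reference_mz))
    vapply(reference_mz, monoisotopic_mz, numeric(1)) else as.numeric(reference_mz)
  if (length(mz) < 2L) stop("need at least 2 reference ions")
  if (any(duplicated(round(mz, 4))))
    stop("degenerate (duplicated) reference ions")

  corrected <- correct_dead_time(spectrum)
  a0 <- params$calib_a; t00 <- params$calib_t0
  n <- length(corrected)

  centroids <- vapply(seq_along(mz), function(k) {
    m <- mz[k]
    lo <- max(1L, floor(tof_bin_of_mz(m - search_window, a0, t00)))
    hi <- min(n, ceiling(tof_bin_of_mz(m + search_window, a0, t00)))
    if (hi - lo < 4L)
      stop("search window for reference ", labels[k], " falls outside the spectrum")
    seg <- corrected[lo:hi]
    sig_bins <- peak_sigma_mz(m, params$resolution) * a0 / (2 * sqrt(m))
    # a reference must stand out as a peak, not just as Poisson baseline:
    # variance-stabilized, matched-kernel-smoothed prominence >= 6 MADs
    z <- gauss_smooth(2 * sqrt(pmax(seg, 0) + 0.375), max(sig_bins, 1))
    half <- ceiling(3 * max(sig_bins, 1))       # drop unsmoothed edges
    core <- (half + 1):(length(z) - half)
    zc <- z[core]
    prominent <- (max(zc) - stats::median(zc)) >= 6 * stats::mad(zc)
    if (sum(seg) < min_counts || !prominent)
      stop("reference ion ", labels[k],
           " not found above noise in its search window")
    peak_bin <- lo - 1L + core[which.max(zc)]
    peak_centroid_bin(corrected, peak_bin, max(3, 3 * sig_bins))
  }, numeric(1))
  if (anyNA(centroids)) stop("centroid estimation failed for a reference ion")

  fit <- fit_tof_law(centroids, mz)

  acc <- NA_real_
  if (length(mz) >= 3L) {
    res <- vapply(seq_along(mz), function(k) {
      f <- fit_tof_law(centroids[-k], mz[-k])
      abs(tof_mz_of_bin(centroids[k], f$a, f$t0) - mz[k])
    }, numeric(1))
    acc <- max(res)
  }
  calibration_model(fit$a, fit$t0,
                    references = data.frame(label = labels, mz = mz,
                                            centroid_bin = centroids,
                                            stringsAsFactors = FALSE),
                    achieved_accuracy = acc)
}

# Least squares for t = a*sqrt(m) + t0 given matched (centroid bin, m/z).
fit_tof_law <- function(bins, mz) {
  x <- sqrt(mz)
  cf <- stats::lm.fit(cbind(x, 1), bins)$coefficients
  list(a = unname(cf[1]), t0 = unname(cf[2]))
}

#' Default internal calibrant m/z values
#'
#' H3(18O)+ (21.0221 Th, always present as the primary-ion isotopologue),
#' protonated acetone C3H7O+ (59.0491 Th, ubiquitous in headspace work) and
#' protonated monoterpene C10H17+ (137.1328 Th) to span the acquired range.
#' @return Named numeric vector of m/z in Th.
#' @export
default_reference_mz <- function() {
  c("H3[18O]+" = monoisotopic_mz("H3[18O]+"),
    "C3H7O+" = monoisotopic_mz("C3H7O+"),
    "C10H17+" = monoisotopic_mz("C10H17+"))
}

#' m/z axis of a calibrated spectrum
#'
#' Applies `m/z(i) = ((i - t0)/a)^2`, strictly increasing for bins past t0.
#'
#' @param model a [calibration_model()].
#' @param bins bin indices (may be fractional centroids).
#' @return m/z values in Th.
#' @seealso [bin_of_mz()] for the inverse.
#' @export
mz_axis <- function(model, bins) {
  stopifnot(inherits(model, "calibration_model"))
  tof_mz_of_bin(bins, model$a, model$t0)
}

#' @rdname mz_axis
#' @param mz m/z values in Th.
#' @export
bin_of_mz <- function(model, mz) {
  stopifnot(inherits(model, "calibration_model"))
  tof_bin_of_mz(mz, model$a, model$t0)
}

#' Serialize / restore a calibration model as JSON
#' @param model a [calibration_model()].
#' @param path file path.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(list(schema = "ptrscreen/calibration/1",
                            a = model$a, t0 = model$t0,
                            achieved_accuracy = model$achieved_accuracy,
                            references = model$references),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "ptrscreen/calibration/1"))
    stop("unsupported calibration schema: ", x$schema)
  calibration_model(x$a, x$t0, references = x$references,
                    achieved_accuracy = x$achieved_accuracy %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
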