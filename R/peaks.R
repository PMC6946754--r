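# Noise reduction, baseline removal, peak detection and modified-Gaussian
# peak fitting.

#' Baseline estimation and removal
#'
#' Estimates the baseline as a smoothed moving low-percentile (default 10th)
#' of the counts, evaluated on contiguous windows and linearly interpolated
#' back to the full axis; the subtraction is clipped at zero.
#'
#' @param counts numeric vector of (dead-time-corrected) counts per bin.
#' @param window window length in bins (default 1000, >= 3).
#' @param prob percentile used for the baseline (default 0.10).
#' @return List with `signal` (baseline-subtracted, clipped at 0) and
#'   `baseline` (the estimate, same length, for audit).
#' @export
remove_baseline <- function(counts, window = 1000, prob = 0.10) {
  n <- length(counts)
  if (window < 3) stop("window must be at least 3 bins")
  if (window > n) stop("baseline window larger than the spectrum")
  starts <- seq(1L, n, by = window)
  q <- vapply(starts, function(s)
    stats::quantile(counts[s:min(s + window - 1L, n)], prob, names = FALSE),
    numeric(1))
  centers <- pmin(starts + (window - 1) / 2, n)
  if (length(q) >= 3) q <- stats::filter(q, rep(1 / 3, 3), sides = 2) |>
      (\(x) ifelse(is.na(x), q, x))()
  baseline <- if (length(q) == 1L) rep(q, n)
              else stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
  list(signal = pmax(counts - baseline, 0), baseline = baseline)
}

# Chunked robust statistic (default MAD * 1.4826), interpolated over the
# axis.
local_stat <- function(signal, window = 1000, stat = stats::mad) {
  n <- length(signal)
  window <- min(window, n)
  starts <- seq(1L, n, by = window)
  s <- vapply(starts, function(st)
    stat(signal[st:min(st + window - 1L, n)]), numeric(1))
  centers <- pmin(starts + (window - 1) / 2, n)
  if (length(s) == 1L) rep(s, n)
  else stats::approx(centers, s, xout = seq_len(n), rule = 2)$y
}

local_noise <- function(signal, window = 1000) {
  pmax(local_stat(signal, window, stats::mad), 1e-9)
}

# Gaussian smoothing with a kernel matched to the expected peak width,
# applied chunkwise because the width (in bins) grows like sqrt(m).
smooth_matched <- function(signal, params, n_chunks = 16L) {
  n <- length(signal)
  out <- numeric(n)
  bounds <- unique(round(seq(1, n + 1, length.out = n_chunks + 1)))
  a <- params$calib_a; t0 <- params$calib_t0
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]; hi <- bounds[k + 1L] - 1L
    mid <- (lo + hi) / 2
    sig_bins <- if (mid > t0 + 1) {
      m <- tof_mz_of_bin(mid, a, t0)
      peak_sigma_mz(m, params$resolution) * a / (2 * sqrt(m))
    } else 2
    sig_bins <- max(sig_bins, 1)
    half <- ceiling(3 * sig_bins)
    w <- stats::dnorm(-half:half, 0, sig_bins)
    w <- w / sum(w)
    slo <- max(1L, lo - half); shi <- min(n, hi + half)
    sm <- stats::filter(signal[slo:shi], w, sides = 2)
    seg <- sm[(lo - slo + 1L):(hi - slo + 1L)]
    seg[is.na(seg)] <- signal[lo:hi][is.na(seg)]
    out[lo:hi] <- seg
  }
  out
}

#' Detect candidate peaks
#'
#' Local maxima of the noise-reduced (matched-kernel smoothed),
#' baseline-subtracted signal with height at least `snr` times the local
#' robust noise (chunked MAD x 1.4826). Maxima closer than half the
#' expected resolution width are merged, keeping the higher (ties: the
#' lower m/z).
#'
#' @param signal baseline-subtracted counts per bin.
#' @param calibration a [calibration_model()] mapping bins to m/z.
#' @param params an [instrument_params()] (resolution, nominal axis).
#' @param snr signal-to-noise detection threshold (default 3).
#' @param noise_window window for the local noise estimate, bins. The
#'   default (5000) keeps the MAD estimation error small relative to the
#'   smoothing correlation length, so the SNR threshold keeps its nominal
#'   tail probability.
#' @return data.frame with `bin` (index of the maximum) and `mz`; zero rows
#'   when nothing exceeds the threshold.
#' @export
# Detection field: variance-stabilized (Anscombe) counts smoothed with the
# matched kernel, plus their local floor (median) and noise (MAD) — shared
# by full-axis detection and targeted extraction so one SNR threshold has
# one meaning.
detection_field <- function(signal, params, noise_window = 5000) {
  sm <- smooth_matched(2 * sqrt(pmax(signal, 0) + 0.375), params)
  list(sm = sm,
       noise = local_noise(sm, noise_window),
       floor = local_stat(sm, noise_window, stats::median))
}

detect_peaks <- function(signal, calibration, params, snr = 3,
                         noise_window = 5000) {
  n <- length(signal)
  fld <- detection_field(signal, params, noise_window)
  sm <- fld$sm; noise <- fld$noise; floor_ <- fld$floor
  i <- 2:(n - 1)
  is_max <- sm[i] > sm[i - 1] & sm[i] >= sm[i + 1] &
    (sm[i] - floor_[i]) >= snr * noise[i]
  cand <- i[is_max]
  # restrict to the acquired mass range
  blo <- tof_bin_of_mz(params$mz_range[1], calibration$a, calibration$t0)
  bhi <- tof_bin_of_mz(params$mz_range[2], calibration$a, calibration$t0)
  cand <- cand[cand > max(calibration$t0 + 1, blo) & cand <= bhi]
  if (!length(cand))
    return(data.frame(bin = integer(), mz = numeric()))
  mz <- mz_axis(calibration, cand)

  # merge maxima closer than half the resolution FWHM
  keep <- logical(length(cand))
  ord <- order(mz)
  cand <- cand[ord]; mz <- mz[ord]
  h <- sm[cand]
  j <- 1L
  while (j <= length(cand)) {
    grp <- j
    while (grp < length(cand) &&
           mz[grp + 1L] - mz[grp] < 0.5 * mz[grp] / params$resolution)
      grp <- grp + 1L
    sel <- j:grp
    best <- sel[order(-h[sel], mz[sel])][1L]
    keep[best] <- TRUE
    j <- grp + 1L
  }
  data.frame(bin = cand[keep], mz = mz[keep])
}

# Modified-Gaussian shape: Gaussian core plus a broader co-centered Gaussian
# wing sharing the center, amplitude fraction `wf` and width multiplier `wm`.
modgauss <- function(x, h, c0, s, wf, wm) {
  h * (exp(-(x - c0)^2 / (2 * s^2)) + wf * exp(-(x - c0)^2 / (2 * (wm * s)^2)))
}

#' Fit modified Gaussians to a spectrum segment
#'
#' Joint nonlinear least squares of a sum of modified Gaussians (Gaussian
#' core + symmetric co-centered broader wing; wing amplitude fraction and
#' width multiplier fitted per peak) over one or more candidate centers.
#' Peaks whose centers lie within `group_sigma` expected widths are fitted
#' jointly. The area is obtained analytically from the fitted parameters,
#' `H*sigma*sqrt(2*pi)*(1 + wf*wm)`, converted to counts per extraction.
#'
#' @param signal baseline-subtracted counts per bin.
#' @param calibration a [calibration_model()].
#' @param centers_bin candidate peak positions (bin indices, e.g. from
#'   [detect_peaks()]).
#' @param params an [instrument_params()].
#' @param n_extractions N_ext of the spectrum (for per-extraction scaling).
#' @param group_sigma grouping distance in expected sigma units (default 4).
#' @param max_restarts bounded restarts on non-convergence before falling
#'   back to a trapezoidal area within +-2 sigma (peak flagged).
#' @param fit_wings fit the wing component (default); `FALSE` pins the wing
#'   fraction at 0, reducing the model to a plain Gaussian.
#' @param weighting `"poisson"` (default; residuals scaled by
#'   `1/sqrt(counts)`, the counting-noise standard deviation) or `"none"`
#'   for plain least squares.
#' @details Peaks fitted jointly in one segment share the width and wing
#'   parameters: they sit within a few resolution widths of each other, so
#'   the instrumental peak shape is common — this keeps strongly
#'   overlapping doublets well conditioned.
#' @return data.frame, one row per fitted peak: `mz`, `area_per_extraction`,
#'   `height`, `sigma`, `wing_frac`, `wing_mult`, `fit_quality`, `fit_ok`.
#'   Peaks with negative fitted amplitude are dropped.
#' @export
fit_modified_gaussian <- function(signal, calibration, centers_bin, params,
                                  n_extractions, group_sigma = 4,
                                  max_restarts = 2L, fit_wings = TRUE,
                                  weighting = c("poisson", "none")) {
  weighting <- match.arg(weighting)
  if (!length(centers_bin))
    return(empty_peak_df())
  centers_bin <- sort(centers_bin)
  mz_c <- mz_axis(calibration, centers_bin)
  sig_c <- peak_sigma_mz(mz_c, params$resolution)

  # deterministic grouping: successive centers within group_sigma widths
  grp <- cumsum(c(1, diff(mz_c) > group_sigma * sig_c[-length(sig_c)]))
  out <- lapply(split(seq_along(centers_bin), grp), function(sel) {
    fit_segment(signal, calibration, centers_bin[sel], mz_c[sel], sig_c[sel],
                params, n_extractions, max_restarts, fit_wings, weighting)
  })
  res <- do.call(rbind, out)
  res[order(res$mz), , drop = FALSE]
}

empty_peak_df <- function() {
  data.frame(mz = numeric(), area_per_extraction = numeric(),
             height = numeric(), sigma = numeric(), wing_frac = numeric(),
             wing_mult = numeric(), fit_quality = numeric(),
             fit_ok = logical())
}

fit_segment <- function(signal, calibration, bins, mz_c, sig_c, params,
                        n_extractions, max_restarts, fit_wings = TRUE,
                        weighting = "poisson") {
  n <- length(signal)
  lo <- max(1L, floor(min(bins) - 6 * sig_c[1] *
                        calibration$a / (2 * sqrt(mz_c[1]))))
  hi <- min(n, ceiling(max(bins) + 6 * sig_c[length(sig_c)] *
                         calibration$a / (2 * sqrt(mz_c[length(mz_c)]))))
  lo <- max(lo, floor(calibration$t0) + 2L)
  x <- mz_axis(calibration, lo:hi)
  y <- signal[lo:hi]
  npk <- length(mz_c)
  if (length(x) < 5 * npk) return(empty_peak_df())

  off0 <- stats::median(y)
  h0 <- pmax(signal[bins] - off0, 1e-6)
  sig0 <- mean(sig_c)
  wf0 <- if (fit_wings) 0.05 else 0
  wf_hi <- if (fit_wings) 0.5 else 0
  wt <- if (weighting == "poisson") 1 / sqrt(pmax(y, 1)) else rep(1, length(y))

  # parameters: offset, shared sigma, shared wing fraction, shared wing
  # width multiplier, then (height, center) per peak
  par0 <- c(off0, sig0, wf0, 2.5, as.numeric(rbind(h0, mz_c)))
  lower <- c(-max(y, 1), sig0 / 4, 0, 1.5,
             as.numeric(rbind(0, mz_c - 3 * sig_c)))
  upper <- c(max(y, 1), sig0 * 4, wf_hi, 6,
             as.numeric(rbind(h0 * 10 + 10, mz_c + 3 * sig_c)))

  model <- function(p) {
    m <- matrix(p[-(1:4)], nrow = 2)
    rowsum <- p[1]
    for (k in seq_len(ncol(m)))
      rowsum <- rowsum + modgauss(x, m[1, k], m[2, k], p[2], p[3], p[4])
    rowsum
  }
  resid_fn <- function(p) (model(p) - y) * wt

  fit <- NULL
  for (try in 0:max_restarts) {
    p_start <- par0
    if (try > 0) {  # deterministic perturbation of the starts
      p_start[2] <- p_start[2] * (1 + 0.3 * try)
      p_start[seq(5, length(p_start), by = 2)] <-
        p_start[seq(5, length(p_start), by = 2)] * (1 + 0.2 * try)
    }
    f <- tryCatch(minpack.lm::nls.lm(p_start, lower, upper, resid_fn,
                                     control = minpack.lm::nls.lm.control(
                                       maxiter = 200)),
                  error = function(e) NULL)
    if (!is.null(f) && f$info %in% 1:4) { fit <- f; break }
  }

  dmz_bin <- function(c0) 2 * sqrt(c0) / calibration$a  # d(mz)/d(bin)

  if (is.null(fit)) {                # fallback: trapezoid within +-2 sigma
    rows <- lapply(seq_len(npk), function(k) {
      inwin <- abs(x - mz_c[k]) <= 2 * sig_c[k]
      if (sum(inwin) < 2) return(NULL)
      area_counts <- sum(y[inwin] - off0) / 0.9545  # correct for the 2-sigma cut
      data.frame(mz = mz_c[k],
                 area_per_extraction = area_counts / n_extractions,
                 height = max(y[inwin]) / n_extractions,
                 sigma = sig_c[k], wing_frac = NA_real_,
                 wing_mult = NA_real_, fit_quality = NA_real_,
                 fit_ok = FALSE)
    })
    return(do.call(rbind, rows) %||% empty_peak_df())
  }

  s <- fit$par[2]; wf <- fit$par[3]; wm <- fit$par[4]
  m <- matrix(fit$par[-(1:4)], nrow = 2)
  r <- model(fit$par) - y
  dof <- max(length(y) - length(fit$par), 1)
  quality <- sum(r^2 / pmax(abs(y), 1)) / dof    # Poisson-scaled reduced stat
  rows <- lapply(seq_len(npk), function(k) {
    h <- m[1, k]; c0 <- m[2, k]
    if (h <= 0) return(NULL)                     # negative/zero amplitude
    area_counts <- h * s * sqrt(2 * pi) * (1 + wf * wm) / dmz_bin(c0)
    data.frame(mz = c0, area_per_extraction = area_counts / n_extractions,
               height = h * (1 + wf) / n_extractions, sigma = s,
               wing_frac = wf, wing_mult = wm, fit_quality = quality,
               fit_ok = TRUE)
  })
  do.call(rbind, rows) %||% empty_peak_df()
}

#' Process one spectrum into a peak table
#'
#' Composes the full per-spectrum chain: dead-time correction, baseline
#' removal, peak detection, modified-Gaussian fitting and (optionally)
#' sum-formula annotation. Deterministic given the inputs and settings;
#' processing provenance is recorded as attributes.
#'
#' @param spectrum a [raw_spectrum()].
#' @param calibration a [calibration_model()]; computed internally with the
#'   default reference ions when `NULL`.
#' @param quant a [quant_params()]; used to extract the primary-ion
#'   intensity (isotopologue convention) attached as attribute
#'   `"primary_intensity"`.
#' @param snr detection threshold (default 3).
#' @param baseline_window baseline window, bins.
#' @param annotate_tol sum-formula annotation tolerance, Th; `NA` disables
#'   annotation.
#' @param element_bounds bounds for [annotate_mz()].
#' @return data.frame of class `peak_table`, rows sorted by m/z, columns
#'   `mz`, `area_per_extraction`, `height`, `sigma`, `wing_frac`,
#'   `wing_mult`, `fit_quality`, `fit_ok`, `formula`, `delta_mz`; attributes
#'   `vial`, `primary_intensity`, `provenance`.
#' @export
integrate_table <- function(spectrum, calibration = NULL,
                            quant = quant_params(), snr = 3,
                            baseline_window = 1000, annotate_tol = 0.005,
                            element_bounds = c(C = 10, H = 20, O = 3, N = 2)) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  params <- spectrum$params
  if (is.null(params)) stop("spectrum carries no instrument params")
  if (is.null(calibration)) calibration <- calibrate(spectrum)
  corrected <- correct_dead_time(spectrum)
  bl <- remove_baseline(corrected, baseline_window)
  cand <- detect_peaks(bl$signal, calibration, params, snr = snr)
  pk <- fit_modified_gaussian(bl$signal, calibration, cand$bin, params,
                              spectrum$n_extractions)
  if (nrow(pk) && !is.na(annotate_tol)) {
    ann <- lapply(pk$mz, annotate_mz, tolerance = annotate_tol,
                  element_bounds = element_bounds)
    pk$formula <- vapply(ann, function(a)
      if (nrow(a)) a$formula[1] else NA_character_, character(1))
    pk$delta_mz <- vapply(ann, function(a)
      if (nrow(a)) a$delta_mz[1] else NA_real_, numeric(1))
  } else if (nrow(pk)) {
    pk$formula <- NA_character_; pk$delta_mz <- NA_real_
  } else {
    pk$formula <- character(); pk$delta_mz <- numeric()
  }
  finish_peak_table(pk, spectrum, calibration, quant,
                    list(mode = "full", snr = snr,
                         baseline_window = baseline_window,
                         annotate_tol = annotate_tol))
}

#' Targeted peak extraction at specified ions
#'
#' Fast path for screening runs: fits one modified Gaussian in a window
#' around each target ion instead of scanning the whole axis. Targets whose
#' window holds no signal above `snr` times the local noise are reported as
#' below LOD (omitted from the table; [build_emission_table()] turns absent
#' targets into flagged zeros).
#'
#' @param spectrum a [raw_spectrum()].
#' @param targets character vector of Hill formulas or numeric m/z values.
#' @param calibration a [calibration_model()] (default: internal
#'   calibration with the default references).
#' @param quant a [quant_params()].
#' @param snr detection threshold within the target window (default 3).
#' @param baseline_window baseline window, bins.
#' @return A `peak_table` (see [integrate_table()]); `formula` filled from
#'   the targets.
#' @export
extract_targets <- function(spectrum, targets, calibration = NULL,
                            quant = quant_params(), snr = 3,
                            baseline_window = 1000) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  params <- spectrum$params
  if (is.null(params)) stop("spectrum carries no instrument params")
  if (is.null(calibration)) calibration <- calibrate(spectrum)
  corrected <- correct_dead_time(spectrum)
  bl <- remove_baseline(corrected, baseline_window)
  fld <- detection_field(bl$signal, params)

  t_mz <- if (is.character(targets))
    vapply(targets, monoisotopic_mz, numeric(1)) else as.numeric(targets)
  t_formula <- if (is.character(targets)) targets else rep(NA_character_,
                                                           length(targets))
  # the primary-ion isotopologue is always extracted (quantification anchor)
  if (!is.null(quant) && quant$primary_mode == "isotopologue" &&
      !any(abs(t_mz - mz_h3o18()) < 0.01)) {
    t_mz <- c(mz_h3o18(), t_mz)
    t_formula <- c("H3[18O]+", t_formula)
  }
  rows <- lapply(seq_along(t_mz), function(k) {
    m <- t_mz[k]
    sig <- peak_sigma_mz(m, params$resolution)
    lo <- max(1L, floor(bin_of_mz(calibration, m - 6 * sig)))
    hi <- min(params$n_bins, ceiling(bin_of_mz(calibration, m + 6 * sig)))
    if (hi - lo < 5) return(NULL)
    seg <- fld$sm[lo:hi]
    pk_bin <- lo - 1L + which.max(seg)
    if (fld$sm[pk_bin] - fld$floor[pk_bin] < snr * fld$noise[pk_bin])
      return(NULL)                                        # below LOD
    fit <- fit_modified_gaussian(bl$signal, calibration, pk_bin, params,
                                 spectrum$n_extractions)
    if (!nrow(fit)) return(NULL)
    fit$formula <- t_formula[k]
    fit$delta_mz <- fit$mz - m
    fit
  })
  pk <- do.call(rbind, rows)
  if (is.null(pk)) {
    pk <- empty_peak_df(); pk$formula <- character(); pk$delta_mz <- numeric()
  }
  finish_peak_table(pk, spectrum, calibration, quant,
                    list(mode = "targeted", snr = snr,
                         baseline_window = baseline_window))
}

finish_peak_table <- function(pk, spectrum, calibration, quant, provenance) {
  pk <- pk[order(pk$mz), , drop = FALSE]
  rownames(pk) <- NULL
  primary <- NA_real_
  if (!is.null(quant)) {
    iso_mz <- mz_h3o18()
    j <- which(abs(pk$mz - iso_mz) <= 0.01)
    if (length(j)) {
      iso <- pk$area_per_extraction[j[which.max(pk$area_per_extraction[j])]]
      primary <- if (quant$primary_mode == "isotopologue")
        iso * quant$isotope_ratio else iso
    }
  }
  structure(pk, class = c("peak_table", "data.frame"),
            vial = spectrum$vial_id, primary_intensity = primary,
            n_extractions = spectrum$n_extractions,
            calibration = calibration, provenance = provenance)
}

#' Write a peak table to CSV (bit-stable ordering)
#'
#' @param pk a `peak_table`.
#' @param path output file.
#' @export
write_peak_table <- function(pk, path) {
  df <- as.data.frame(pk)
  df <- cbind(vial = attr(pk, "vial"), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
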