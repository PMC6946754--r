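# Synthetic ToF spectra and whole screening experiments.
#
# The forward model inverts the processing chain: mixing ratios are turned
# into expected count rates through the same proton-transfer kinetics used
# for quantification, counts are spread over flight-time bins as a Gaussian
# of constant m/dm width mapped through the ToF law, Poisson baseline is
# added, and registered counts are drawn under the non-paralyzable
# dead-time censoring model that the Poisson correction inverts.

#' Define an ion source for the simulator
#'
#' @param formula_or_mz Hill formula string (e.g. `"C5H9+"`) or a bare m/z
#'   in Th for unannotated sources.
#' @param ppbv headspace mixing ratio in ppbv (for analytes); converted to a
#'   count rate through the kinetic quantification formula.
#' @param count_rate direct count rate in counts/s (for calibrant or
#'   instrument-background ions); exactly one of `ppbv`/`count_rate` must be
#'   given.
#' @return Object of class `ion_source`.
#' @export
ion_source <- function(formula_or_mz, ppbv = NULL, count_rate = NULL) {
  if (is.null(ppbv) == is.null(count_rate))
    stop("give exactly one of `ppbv` or `count_rate`")
  if (!is.null(ppbv) && ppbv < 0) stop("ppbv must be >= 0")
  if (!is.null(count_rate) && count_rate < 0) stop("count_rate must be >= 0")
  if (is.character(formula_or_mz)) {
    formula <- formula_or_mz
    mz <- monoisotopic_mz(formula_or_mz)
  } else {
    formula <- NA_character_
    mz <- as.numeric(formula_or_mz)
  }
  structure(list(formula = formula, mz = mz, ppbv = ppbv,
                 count_rate = count_rate),
            class = "ion_source")
}

# Add an ion's expected per-extraction counts to the lambda vector as a
# Gaussian of width sigma(m) = m/(R * 2.3548) mapped through the ToF law.
add_ion_lambda <- function(lambda, mz, counts_per_extraction, params) {
  if (counts_per_extraction <= 0) return(lambda)
  a <- params$calib_a; t0 <- params$calib_t0
  sig <- peak_sigma_mz(mz, params$resolution)
  lo <- max(1L, floor(tof_bin_of_mz(max(mz - 6 * sig, 1e-6), a, t0)))
  hi <- min(params$n_bins, ceiling(tof_bin_of_mz(mz + 6 * sig, a, t0)))
  if (hi <= lo) return(lambda)
  bins <- lo:hi
  m_i <- tof_mz_of_bin(bins, a, t0)
  w <- stats::dnorm(m_i, mz, sig) * c(diff(m_i), diff(m_i)[length(m_i) - 1])
  w <- w / sum(w)
  lambda[bins] <- lambda[bins] + counts_per_extraction * w
  lambda
}

#' Simulate one raw ToF spectrum
#'
#' @param ions list of [ion_source()] objects (analytes in ppbv and/or
#'   calibrants with direct count rates).
#' @param params an [instrument_params()].
#' @param duration measurement duration in seconds (default 30).
#' @param quant a [quant_params()]; supplies the primary-ion count rate and
#'   the kinetic constants of the ppbv -> count-rate conversion.
#' @param conditions a [drift_conditions()].
#' @param include_primary simulate the H3(18)O+ primary-ion isotopologue
#'   peak at 21.0221 Th (rate = primary rate / isotope ratio). The H3O+
#'   peak itself is not simulated: at realistic source settings it
#'   saturates the detector, which is exactly why quantification uses the
#'   isotopologue. Required (`TRUE`) whenever analyte sources are given in
#'   ppbv.
#' @param vial_id vial identifier carried into the spectrum.
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @return A [raw_spectrum()] with the instrument params attached and the
#'   per-bin expected (uncensored) counts as attribute `"lambda_total"`.
#' @export
simulate_spectrum <- function(ions, params, duration = 30,
                              quant = quant_params(),
                              conditions = drift_conditions(),
                              include_primary = TRUE,
                              vial_id = NA_character_, seed = NULL) {
  stopifnot(inherits(params, "instrument_params"))
  if (duration <= 0) stop("duration must be positive")
  has_ppbv <- any(vapply(ions, function(s) !is.null(s$ppbv), logical(1)))
  if (has_ppbv && !include_primary)
    stop("analyte sources in ppbv require the primary-ion source ",
         "(include_primary = TRUE)")
  if (!is.null(seed)) set.seed(seed)

  n_ext <- params$extraction_rate * duration
  lambda <- rep.int(params$baseline_rate, params$n_bins)

  primary_per_ext <- quant$primary_count_rate / params$extraction_rate
  if (include_primary) {
    iso_rate <- quant$primary_count_rate / quant$isotope_ratio
    lambda <- add_ion_lambda(lambda, mz_h3o18(),
                             iso_rate / params$extraction_rate, params)
  }
  for (s in ions) {
    if (!is.null(s$count_rate)) {
      cpe <- s$count_rate / params$extraction_rate
    } else {
      ratio <- count_ratio_of_ppbv(s$ppbv, quant, conditions,
                                   formula = if (is.na(s$formula)) NULL else s$formula)
      cpe <- ratio * primary_per_ext
    }
    lambda <- add_ion_lambda(lambda, s$mz, cpe, params)
  }

  counts <- censored_counts(lambda, n_ext, params$dead_time_bins)
  out <- raw_spectrum(counts, n_extractions = n_ext,
                      dead_time_bins = params$dead_time_bins,
                      duration = duration, vial_id = vial_id,
                      params = params)
  attr(out, "lambda_total") <- lambda * n_ext
  out
}

#' Screening experiment design
#'
#' Study layout of a transgenic-line emission screen: many independent
#' lines with strongly right-skewed true emissions, measured one leaf per
#' vial in autosampler blocks that each carry one wild-type (Col-0)
#' reference, in randomized order; transgene expression only weakly
#' correlated with realized emission.
#'
#' @param n_lines number of independent transgenic lines (default 116).
#' @param block_size vials per autosampler block (default 32).
#' @param col0_per_block Col-0 reference vials per block (default 1).
#' @param emission_meanlog,emission_sdlog log-normal parameters of the true
#'   isoprene emission across lines, ppbv per mg fresh weight. Defaults
#'   `log(5)` and `0.512` give a median of 5 and population skewness of
#'   about 1.8.
#' @param background_emission Col-0 (non-transgenic) isoprene background,
#'   ppbv/mgFW (default 0.14).
#' @param expression_r2 target squared correlation between transgene
#'   expression (qPCR fold change) and emission among the
#'   `expression_top_k` top-emitting lines (default 0.28).
#' @param expression_top_k number of top lines over which the expression
#'   noise is calibrated (default 29).
#' @param expression_slope slope of expression on emission before noise
#'   (default 1: fold change on the emission scale).
#' @param fw_mean,fw_sd leaf fresh weight distribution, mg (default 20, 3).
#' @param calibrant_ppbv named numeric vector of constant calibrant-ion
#'   mixing ratios added to every vial (defaults: protonated acetone
#'   10 ppbv, C10H17+ 5 ppbv).
#' @param analyte_ion Hill formula of the screened product ion (default
#'   protonated isoprene `"C5H9+"`).
#' @param seed integer RNG seed making the whole experiment reproducible.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(n_lines = 116, block_size = 32,
                              col0_per_block = 1,
                              emission_meanlog = log(5),
                              emission_sdlog = 0.512,
                              background_emission = 0.14,
                              expression_r2 = 0.28,
                              expression_top_k = 29,
                              expression_slope = 1,
                              fw_mean = 20, fw_sd = 3,
                              calibrant_ppbv = c("C3H7O+" = 10,
                                                 "C10H17+" = 5),
                              analyte_ion = "C5H9+",
                              seed = 1L) {
  stopifnot(n_lines >= 1, block_size >= 2, col0_per_block >= 1,
            emission_sdlog > 0, fw_mean > 0, fw_sd > 0,
            expression_r2 > 0, expression_r2 < 1,
            expression_top_k >= 3, background_emission >= 0)
  if (block_size < col0_per_block + 1)
    stop("block_size must exceed col0_per_block (need room for lines)")
  structure(as.list(environment()), class = "experiment_design")
}

#' Simulate a whole screening experiment
#'
#' Draws per-line true emissions and expression, packs lines into
#' autosampler blocks (each with its Col-0 reference), randomizes the
#' measurement order across the run, and simulates one raw spectrum per
#' vial.
#'
#' @param design an [experiment_design()].
#' @param params an [instrument_params()].
#' @param quant a [quant_params()].
#' @param conditions a [drift_conditions()].
#' @param duration per-vial measurement duration, s (default 30).
#' @param spectra simulate the raw spectra (default); `FALSE` returns the
#'   design-level truth only (cheap, for calibrating the generator itself).
#' @return List with elements
#'   `spectra` (named list of [raw_spectrum()] by vial ID, or `NULL`),
#'   `samples` (data.frame: vial, line, genotype, block, fw_mg, order),
#'   `expression` (data.frame: line, fold_change),
#'   `truth` (data.frame: line, true_emission ppbv/mgFW, true_ppbv, fw_mg),
#'   and the `design`.
#' @export
simulate_experiment <- function(design, params = instrument_params(),
                                quant = quant_params(),
                                conditions = drift_conditions(),
                                duration = 30, spectra = TRUE) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)

  n <- design$n_lines
  lines <- sprintf("L%03d", seq_len(n))
  emission <- stats::rlnorm(n, design$emission_meanlog, design$emission_sdlog)

  # expression: linear in true emission plus noise sized so that the
  # squared correlation among the top-k emitters is expression_r2
  top_k <- order(emission, decreasing = TRUE)[seq_len(min(design$expression_top_k, n))]
  v_top <- stats::var(emission[top_k])
  tau <- sqrt(design$expression_slope^2 * v_top *
                (1 / design$expression_r2 - 1))
  fold <- design$expression_slope * emission + stats::rnorm(n, 0, tau)
  fold <- pmax(fold, 1e-3)                      # fold changes are positive

  # pack into blocks: block_size vials each, col0_per_block references
  per_block <- design$block_size - design$col0_per_block
  n_blocks <- ceiling(n / per_block)
  vial_rows <- list()
  idx <- 1L
  for (b in seq_len(n_blocks)) {
    take <- lines[idx:min(idx + per_block - 1L, n)]
    idx <- idx + length(take)
    block_lines <- c(take, rep("Col-0", design$col0_per_block))
    vial_rows[[b]] <- data.frame(
      line = block_lines,
      genotype = ifelse(block_lines == "Col-0", "Col-0", "transgenic"),
      block = b, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, vial_rows)
  samples$vial <- sprintf("V%03d", seq_len(nrow(samples)))
  samples$fw_mg <- pmax(stats::rnorm(nrow(samples), design$fw_mean,
                                     design$fw_sd), 1)
  samples$order <- sample.int(nrow(samples))    # randomized measurement order
  samples <- samples[c("vial", "line", "genotype", "block", "fw_mg", "order")]

  emission_of <- stats::setNames(emission, lines)
  spec_list <- NULL
  if (isTRUE(spectra)) {
    calibrants <- lapply(names(design$calibrant_ppbv), function(f)
      ion_source(f, ppbv = design$calibrant_ppbv[[f]]))
    spec_list <- vector("list", nrow(samples))
    names(spec_list) <- samples$vial
    for (i in seq_len(nrow(samples))) {
      em <- if (samples$line[i] == "Col-0") design$background_emission
            else emission_of[[samples$line[i]]]
      ppbv <- em * samples$fw_mg[i]
      ions <- c(calibrants, list(ion_source(design$analyte_ion, ppbv = ppbv)))
      spec_list[[i]] <- simulate_spectrum(ions, params, duration = duration,
                                          quant = quant,
                                          conditions = conditions,
                                          vial_id = samples$vial[i])
    }
  }

  truth <- data.frame(line = lines, true_emission = emission,
                      fold_change = fold, stringsAsFactors = FALSE)
  truth$fw_mg <- samples$fw_mg[match(truth$line, samples$line)]
  truth$true_ppbv <- truth$true_emission * truth$fw_mg

  list(spectra = spec_list, samples = samples,
       expression = data.frame(line = lines, fold_change = fold,
                               stringsAsFactors = FALSE),
       truth = truth, design = design)
}

#' Random multi-ion panel for detection tests
#'
#' Generates `n_ions` well-separated sources across an m/z range with
#' log-uniform count rates, emulating the ~184-peak VOC panel a leaf
#' headspace shows in m/z 15-300.
#'
#' @param n_ions number of ions (default 184).
#' @param mz_range m/z range, Th.
#' @param rate_range count-rate range, counts/s (log-uniform).
#' @param min_sep_sigma minimum separation between neighbours in units of
#'   the local peak sigma (default 8: fully resolved panel).
#' @param seed optional seed.
#' @param resolution resolving power used for the separation rule.
#' @return List of [ion_source()] objects.
#' @export
synthetic_panel <- function(n_ions = 184, mz_range = c(15, 300),
                            rate_range = c(200, 20000),
                            min_sep_sigma = 8, seed = NULL,
                            resolution = 7000) {
  if (!is.null(seed)) set.seed(seed)
  mz <- sort(stats::runif(5 * n_ions, mz_range[1], mz_range[2]))
  keep <- c()
  last <- -Inf
  for (m in mz) {
    if (m - last >= min_sep_sigma * peak_sigma_mz(m, resolution)) {
      keep <- c(keep, m); last <- m
    }
    if (length(keep) == n_ions) break
  }
  if (length(keep) < n_ions)
    stop("could not place ", n_ions, " ions at the requested separation")
  rate <- exp(stats::runif(n_ions, log(rate_range[1]), log(rate_range[2])))
  mapply(function(m, r) ion_source(m, count_rate = r),
         keep, rate, SIMPLIFY = FALSE)
}
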