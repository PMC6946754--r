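# Spectrum container, run configuration, pipeline composition.
#
# The container is a run directory: a JSON manifest (schema version,
# instrument params, per-spectrum metadata) plus one sparse CSV
# (bin,count over the nonzero bins) per spectrum — a lossless,
# self-describing plain-text round-trip for integer count histograms.

SPECTRA_SCHEMA <- "ptrscreen/spectra/1"

params_to_list <- function(p) {
  unclass(p)
}

params_from_list <- function(x) {
  instrument_params(calib_a = x$calib_a, calib_t0 = x$calib_t0,
                    resolution = x$resolution,
                    mz_range = as.numeric(x$mz_range), n_bins = x$n_bins,
                    dead_time_bins = x$dead_time_bins,
                    extraction_rate = x$extraction_rate,
                    baseline_rate = x$baseline_rate)
}

# write file atomically: temp file in the same directory, then rename
atomic_write <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

#' Write a collection of raw spectra to a run directory
#'
#' @param spectra named list of [raw_spectrum()] (names = vial IDs, or
#'   taken from each spectrum's `vial_id`).
#' @param path run directory (created if needed).
#' @param params an [instrument_params()]; taken from the first spectrum
#'   when `NULL`. Required when `spectra` is empty.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, params = NULL) {
  if (is.null(params)) {
    if (!length(spectra)) stop("params required for an empty container")
    params <- spectra[[1]]$params
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- names(spectra) %||% vapply(spectra, function(s) s$vial_id, character(1))
  if (anyNA(ids) || anyDuplicated(ids))
    stop("spectra need unique vial IDs")
  meta <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    list(vial = ids[i], n_extractions = s$n_extractions,
         dead_time_bins = s$dead_time_bins, duration = s$duration,
         n_bins = length(s$counts), file = paste0(ids[i], ".csv"))
  })
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    nz <- which(s$counts > 0L)
    df <- data.frame(bin = nz, count = s$counts[nz])
    atomic_write(function(tmp) utils::write.csv(df, tmp, row.names = FALSE),
                 file.path(path, meta[[i]]$file))
  }
  atomic_write(function(tmp)
    jsonlite::write_json(list(schema = SPECTRA_SCHEMA,
                              params = params_to_list(params),
                              spectra = meta),
                         tmp, auto_unbox = TRUE, digits = NA),
    file.path(path, "manifest.json"))
  invisible(path)
}

#' @rdname write_spectra
#' @return `read_spectra`: list with `spectra` (named list of
#'   [raw_spectrum()]) and `params`.
#' @export
read_spectra <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path,
                             ": not a spectrum container")
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (!identical(man$schema, SPECTRA_SCHEMA))
    stop("unsupported container schema: ", man$schema %||% "<missing>")
  params <- params_from_list(man$params)
  spectra <- lapply(man$spectra, function(m) {
    f <- file.path(path, m$file)
    if (!file.exists(f)) stop("container truncated: missing ", m$file)
    df <- utils::read.csv(f)
    counts <- integer(m$n_bins)
    counts[df$bin] <- as.integer(df$count)
    raw_spectrum(counts, n_extractions = m$n_extractions,
                 dead_time_bins = m$dead_time_bins, duration = m$duration,
                 vial_id = m$vial, params = params)
  })
  names(spectra) <- vapply(man$spectra, `[[`, character(1), "vial")
  list(spectra = spectra, params = params)
}

#' Assemble a run configuration
#'
#' Bundles every tunable of the pipeline with its defaults; all defaults
#' trace either to the standard screening operating point or to documented
#' package decisions.
#'
#' @param params an [instrument_params()].
#' @param conditions a [drift_conditions()].
#' @param quant a [quant_params()].
#' @param design an [experiment_design()].
#' @param target_ions Hill formulas of the quantified ions.
#' @param snr detection threshold.
#' @param baseline_window baseline window, bins.
#' @param alpha significance level; `family` Bonferroni family size
#'   (`NULL` = number of target ions); `n_boot` bootstrap replicates.
#' @param seed run seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(params = instrument_params(),
                       conditions = drift_conditions(),
                       quant = quant_params(),
                       design = experiment_design(),
                       target_ions = c("C5H9+"),
                       snr = 3, baseline_window = 1000,
                       alpha = 0.05, family = NULL, n_boot = 1999,
                       seed = 1L) {
  structure(list(params = params, conditions = conditions, quant = quant,
                 design = design, target_ions = target_ions, snr = snr,
                 baseline_window = baseline_window, alpha = alpha,
                 family = family, n_boot = n_boot, seed = as.integer(seed)),
            class = "run_config")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; recorded in every pipeline
#' output so results are traceable to their exact settings.
#' @param config a [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Process a set of spectra into an emission table
#'
#' Per spectrum: dead-time correction + internal calibration + targeted
#' modified-Gaussian extraction of the target ions (plus the primary-ion
#' isotopologue), then kinetic quantification and fresh-weight
#' normalization against the sample records.
#'
#' @param spectra named list of [raw_spectrum()] (by vial ID).
#' @param samples sample records (`vial`, `line`, `genotype`, `block`,
#'   `fw_mg`).
#' @param target_ions Hill formulas to quantify.
#' @param quant a [quant_params()].
#' @param conditions a [drift_conditions()].
#' @param reference_mz calibration references (default set).
#' @param snr,baseline_window processing settings.
#' @return List with `emissions` (an `emission_table`), `peak_tables`,
#'   `calibrations`.
#' @export
process_experiment <- function(spectra, samples, target_ions,
                               quant = quant_params(),
                               conditions = drift_conditions(),
                               reference_mz = NULL, snr = 3,
                               baseline_window = 1000) {
  cals <- list(); tabs <- list()
  targets <- unique(c(target_ions, "H3[18O]+"))
  for (id in names(spectra)) {
    s <- spectra[[id]]
    cal <- calibrate(s, reference_mz = reference_mz)
    tabs[[id]] <- extract_targets(s, targets, calibration = cal,
                                  quant = quant, snr = snr,
                                  baseline_window = baseline_window)
    cals[[id]] <- cal
  }
  emissions <- build_emission_table(tabs, samples, target_ions,
                                    quant, conditions)
  list(emissions = emissions, peak_tables = tabs, calibrations = cals)
}

#' Write an emission table (long and wide CSV)
#'
#' @param emissions an `emission_table`.
#' @param path_long,path_wide output CSV paths (either may be `NULL`).
#' @export
write_emission_table <- function(emissions, path_long = NULL,
                                 path_wide = NULL) {
  if (!is.null(path_long))
    atomic_write(function(tmp)
      utils::write.csv(as.data.frame(emissions), tmp, row.names = FALSE),
      path_long)
  if (!is.null(path_wide))
    atomic_write(function(tmp)
      utils::write.csv(emission_wide(emissions), tmp, row.names = FALSE),
      path_wide)
  invisible(emissions)
}
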