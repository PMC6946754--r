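# Proton-transfer-reaction kinetic quantification and fresh-weight
# normalization.

#' Boltzmann constant, J/K
#' @keywords internal
.kB <- 1.380649e-23

#' Drift-tube conditions
#'
#' Operating point of the PTR drift tube. The reduced field E/N is always
#' derived from voltage, pressure, temperature and geometry, never set
#' directly. Drift length and the ion reaction time are instrument geometry
#' not printed on the front panel; typical values for the commercial
#' instruments used in VOC screening are 9.3 cm and ~100 us.
#'
#' @param voltage drift voltage, V (default 550).
#' @param pressure drift pressure, mbar (default 2.3).
#' @param temperature drift temperature, degrees C (default 110).
#' @param drift_length drift-tube length, cm (default 9.3).
#' @param reaction_time ion-molecule reaction time, s (default 1e-4).
#' @return Object of class `drift_conditions` with derived fields
#'   `temperature_K`, `number_density` (cm^-3) and `E_over_N` (Td).
#' @export
drift_conditions <- function(voltage = 550, pressure = 2.3,
                             temperature = 110, drift_length = 9.3,
                             reaction_time = 1e-4) {
  stopifnot(voltage > 0, pressure > 0, temperature > -273.15,
            reaction_time > 0)
  if (is.null(drift_length) || is.na(drift_length) || drift_length <= 0)
    stop("drift_length (cm) must be configured: it is instrument geometry, ",
         "not derivable from the drift settings")
  x <- list(voltage = voltage, pressure = pressure,
            temperature = temperature, drift_length = drift_length,
            reaction_time = reaction_time)
  x$temperature_K <- temperature + 273.15
  # N = p / (kB T); pressure mbar -> Pa (x100); m^-3 -> cm^-3 (x1e-6)
  x$number_density <- (pressure * 100) / (.kB * x$temperature_K) * 1e-6
  x$E_over_N <- compute_E_over_N_impl(x)
  structure(x, class = "drift_conditions")
}

compute_E_over_N_impl <- function(x) {
  E <- x$voltage / x$drift_length          # V/cm
  (E / x$number_density) / 1e-17           # Td; 1 Td = 1e-17 V cm^2
}

#' Reduced electric field E/N of the drift tube
#'
#' `E = V / L` with L the drift length; `N = p / (kB T)` the buffer-gas
#' number density. Reported in Townsend (1 Td = 1e-17 V cm^2). At the
#' standard screening settings (550 V, 2.3 mbar, 110 C, 9.3 cm) this is
#' about 136 Td, in the ~140 Td regime where proton-transfer chemistry is
#' clean.
#'
#' @param conditions a [drift_conditions()].
#' @return E/N in Td.
#' @export
compute_E_over_N <- function(conditions) {
  stopifnot(inherits(conditions, "drift_conditions"))
  compute_E_over_N_impl(conditions)
}

#' @export
print.drift_conditions <- function(x, ...) {
  cat(sprintf("<drift_conditions> %g V / %g mbar / %g C, L = %g cm -> E/N = %.1f Td\n",
              x$voltage, x$pressure, x$temperature, x$drift_length, x$E_over_N))
  invisible(x)
}

#' Quantification parameters
#'
#' @param k_default default proton-transfer rate coefficient, cm^3/s
#'   (2e-9, the canonical collision-limit value).
#' @param k_overrides named numeric vector of per-ion rate coefficients,
#'   names are Hill formula strings of the product ion (the "actual rate
#'   coefficient" is compound specific).
#' @param transmission named numeric vector of relative detector/ion-optics
#'   transmission factors per ion formula (default 1 for all).
#' @param primary_mode `"isotopologue"` (measure H3(18)O+ at 21.0221 Th and
#'   scale by `isotope_ratio`; standard practice, the H3O+ peak itself
#'   saturates the detector) or `"direct"`.
#' @param isotope_ratio H3O+/H3(18)O+ abundance ratio (default 487).
#' @param primary_count_rate nominal primary-ion count rate, counts/s,
#'   used by the simulator (default 1e6).
#' @return Object of class `quant_params`.
#' @export
quant_params <- function(k_default = 2e-9, k_overrides = c(),
                         transmission = c(),
                         primary_mode = c("isotopologue", "direct"),
                         isotope_ratio = 487,
                         primary_count_rate = 1e6) {
  stopifnot(k_default > 0, all(k_overrides > 0), all(transmission > 0),
            isotope_ratio > 0, primary_count_rate > 0)
  structure(list(k_default = k_default, k_overrides = k_overrides,
                 transmission = transmission,
                 primary_mode = match.arg(primary_mode),
                 isotope_ratio = isotope_ratio,
                 primary_count_rate = primary_count_rate),
            class = "quant_params")
}

rate_coefficient <- function(params, formula = NULL) {
  if (!is.null(formula) && length(params$k_overrides) &&
      !is.null(names(params$k_overrides)) &&
      formula %in% names(params$k_overrides))
    return(unname(params$k_overrides[[formula]]))
  params$k_default
}

transmission_factor <- function(params, formula = NULL) {
  if (!is.null(formula) && length(params$transmission) &&
      formula %in% names(params$transmission))
    return(unname(params$transmission[[formula]]))
  1
}

#' Headspace concentration from peak intensities
#'
#' Standard PTR-MS kinetic quantification: for product-ion intensity I_R and
#' primary-ion intensity I_H3O+ (both counts per extraction,
#' transmission-corrected), the analyte number density in the drift tube is
#'
#'   `[R] = I_R / (I_H3O+ * k * t_reaction)`  (cm^-3)
#'
#' and the mixing ratio is `[R] / N_drift * 1e9` ppbv. Linear in the analyte
#' intensity, inversely proportional to the primary intensity.
#'
#' @param analyte_intensity counts per extraction of the product ion.
#' @param primary_intensity counts per extraction of H3O+ (already scaled by
#'   the isotope ratio when measured via the 21.0221 Th isotopologue).
#' @param params a [quant_params()].
#' @param conditions a [drift_conditions()].
#' @param formula optional Hill string of the product ion, to pick up
#'   per-ion rate coefficient and transmission overrides.
#' @return Concentration in ppbv (vectorized over `analyte_intensity`).
#' @export
concentration_ppbv <- function(analyte_intensity, primary_intensity,
                               params, conditions, formula = NULL) {
  stopifnot(inherits(params, "quant_params"),
            inherits(conditions, "drift_conditions"))
  if (length(primary_intensity) != 1L || !is.finite(primary_intensity) ||
      primary_intensity <= 0)
    stop("primary-ion intensity must be a positive scalar ",
         "(zero indicates failed primary-ion detection)")
  if (any(analyte_intensity < 0)) stop("negative analyte intensity")
  k <- rate_coefficient(params, formula)
  tr <- transmission_factor(params, formula)
  ratio <- (analyte_intensity / tr) / primary_intensity
  dens <- ratio / (k * conditions$reaction_time)       # cm^-3
  dens / conditions$number_density * 1e9               # ppbv
}

# Inverse of concentration_ppbv: expected product-ion/primary-ion count
# ratio at a given mixing ratio. Used by the simulator forward model.
count_ratio_of_ppbv <- function(ppbv, params, conditions, formula = NULL) {
  k <- rate_coefficient(params, formula)
  tr <- transmission_factor(params, formula)
  ppbv * 1e-9 * conditions$number_density * k * conditions$reaction_time * tr
}

#' Normalize headspace concentration by leaf fresh weight
#'
#' @param ppbv concentration(s) in ppbv.
#' @param fresh_weight_mg leaf fresh weight in mg (> 0).
#' @return ppbv per mg fresh weight.
#' @export
normalize_fw <- function(ppbv, fresh_weight_mg) {
  if (any(!is.finite(fresh_weight_mg)) || any(fresh_weight_mg <= 0))
    stop("fresh weight must be positive and finite (mg)")
  ppbv / fresh_weight_mg
}

#' Build the samples-by-ions emission table
#'
#' Joins per-vial peak tables with sample metadata and reports, for each
#' target ion, the headspace concentration in ppbv and normalized
#' ppbv per mg fresh weight. A target ion with no detected peak within
#' `match_tol` gets 0 with a below-LOD flag. Vials without a usable fresh
#' weight keep their ppbv values but are flagged and carry NA in the
#' normalized columns.
#'
#' @param peak_tables named list (by vial ID) of peak tables as returned by
#'   [integrate_table()] or [extract_targets()].
#' @param samples data.frame of sample records with columns
#'   `vial`, `line`, `genotype`, `block`, `fw_mg` and optionally `order`.
#' @param target_ions character vector of Hill formula strings of the ions
#'   to quantify.
#' @param params a [quant_params()].
#' @param conditions a [drift_conditions()].
#' @param match_tol m/z tolerance for matching a fitted peak to a target
#'   ion, Th (default 0.005).
#' @return A long-format data.frame of class `emission_table` with columns
#'   `vial`, `line`, `genotype`, `block`, `fw_mg`, `ion`, `mz`, `ppbv`,
#'   `ppbv_per_mg`, `below_lod`.
#' @export
build_emission_table <- function(peak_tables, samples, target_ions,
                                 params, conditions, match_tol = 0.005) {
  stopifnot(is.list(peak_tables), is.data.frame(samples))
  need <- c("vial", "line", "genotype", "block", "fw_mg")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$vial))
    stop("duplicate vial IDs in sample records")
  if (length(peak_tables) && is.null(names(peak_tables)))
    stop("peak_tables must be named by vial ID")
  target_mz <- vapply(target_ions, monoisotopic_mz, numeric(1))
  ord <- order(target_mz)                      # deterministic column order
  target_ions <- target_ions[ord]; target_mz <- target_mz[ord]

  rows <- lapply(seq_len(nrow(samples)), function(i) {
    rec <- samples[i, ]
    pt <- peak_tables[[as.character(rec$vial)]]
    if (is.null(pt))
      stop("no peak table for vial ", rec$vial)
    primary <- attr(pt, "primary_intensity")
    if (is.null(primary))
      stop("peak table for vial ", rec$vial, " lacks a primary-ion intensity")
    ppbv <- numeric(length(target_ions))
    lod <- logical(length(target_ions))
    for (k in seq_along(target_ions)) {
      j <- which(abs(pt$mz - target_mz[k]) <= match_tol)
      if (length(j) == 0L) {
        ppbv[k] <- 0; lod[k] <- TRUE
      } else {
        j <- j[which.max(pt$area_per_extraction[j])]
        ppbv[k] <- concentration_ppbv(pt$area_per_extraction[j], primary,
                                      params, conditions,
                                      formula = target_ions[k])
      }
    }
    fw_ok <- is.finite(rec$fw_mg) && rec$fw_mg > 0
    data.frame(vial = rec$vial, line = rec$line, genotype = rec$genotype,
               block = rec$block, fw_mg = rec$fw_mg,
               ion = target_ions, mz = target_mz, ppbv = ppbv,
               ppbv_per_mg = if (fw_ok) ppbv / rec$fw_mg else NA_real_,
               below_lod = lod, fw_missing = !fw_ok,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vial = character(), line = character(),
               genotype = character(), block = integer(),
               fw_mg = numeric(), ion = character(), mz = numeric(),
               ppbv = numeric(), ppbv_per_mg = numeric(),
               below_lod = logical(), fw_missing = logical())
  class(out) <- c("emission_table", "data.frame")
  out
}

#' Reshape an emission table to wide (samples x ions) form
#'
#' @param emissions an `emission_table` (long form).
#' @param value `"ppbv_per_mg"` (default) or `"ppbv"`.
#' @return A data.frame with one row per vial and one column per ion,
#'   metadata columns first.
#' @export
emission_wide <- function(emissions, value = c("ppbv_per_mg", "ppbv")) {
  value <- match.arg(value)
  meta <- unique(emissions[c("vial", "line", "genotype", "block", "fw_mg")])
  ions <- unique(emissions$ion[order(emissions$mz)])
  for (ion in ions) {
    sub <- emissions[emissions$ion == ion, c("vial", value)]
    meta[[ion]] <- sub[[value]][match(meta$vial, sub$vial)]
  }
  meta[order(meta$vial), , drop = FALSE]
}
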