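# Shared fixtures: compact instrument configurations so each test only pays
# for the mass range it needs.

# narrow acquisition window, full bin density: peak-shape fidelity preserved
narrow_params <- function(mz_hi = 80, ...) {
  instrument_params(calib_a = 21000, calib_t0 = 5000, mz_range = c(15, mz_hi),
                    ...)
}

# coarse-binned instrument for count-statistics tests (no peak fitting)
coarse_params <- function(...) {
  instrument_params(calib_a = 3000, calib_t0 = 1200, mz_range = c(15, 80),
                    ...)
}

std_quant <- function(...) quant_params(...)
std_drift <- function(...) drift_conditions(...)

# Ion m/z and printed reference values of the six routinely screened VOC
# product ions (unidentified C4H5+, protonated isoprene, 2-methylbutanal,
# two monoterpene fragments, protonated monoterpenes).
screen_ion_table <- function() {
  data.frame(
    formula = c("C4H5+", "C5H9+", "C5H9O+", "C7H11+", "C8H13+", "C10H17+"),
    printed_mz = c(53.0394, 69.0683, 85.0648, 95.0845, 109.1021, 137.1328),
    stringsAsFactors = FALSE)
}
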