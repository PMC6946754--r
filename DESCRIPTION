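Package: ptrscreen
Title: High-Throughput VOC Emission Screening from PTR-ToF-MS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical screening pipeline for proton transfer
    reaction time-of-flight mass spectrometry (PTR-ToF-MS) volatile organic
    compound (VOC) measurements of plant headspace samples. Converts raw
    time-of-flight ion-count histograms to absolute headspace concentrations
    (ppbv, normalized per mg leaf fresh weight): Poisson-statistics detector
    dead-time correction, internal mass calibration of the flight-time axis,
    baseline removal and modified-Gaussian peak fitting, sum-formula annotation
    of peaks from accurate mass, and kinetic quantification against the H3O+
    primary ion. Includes the screening statistics used to rank transgenic
    lines by emission (Welch one-way tests with Bonferroni correction and
    compact letter displays, distribution diagnostics, bootstrap regression
    bands, emission-profile correlations) and a synthetic-spectrum simulator
    that emulates the instrument and a whole randomized-block screening
    experiment, so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
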