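Package: sipracs
Title: DNA Stable-Isotope Probing and Raman-Activated Cell Sorting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for carbon-13 DNA stable-isotope probing (SIP)
    density-gradient experiments coupled to single-cell Raman-activated cell
    sorting (RACS). Simulates two-treatment (12C/13C) SIP gradients and
    single-cell Raman spectra, models the buoyant-density versus fraction
    relationship, identifies light and heavy DNA windows, computes the
    relative enrichment factor (REF) statistic to call substrate-assimilating
    taxa, classifies cells as isotopically labelled by the phenylalanine-band
    redshift (1001 to 968 1/cm), and emits genome-directed cultivation-medium
    and consortium inoculation-ratio recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
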