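Package: coilsafe
Title: Tier-Based RF Safety Assessment for Custom MRI Transmit Coils
Version: 0.1.0
Authors@R:
    person("Coilsafe", "Developers", email = "coilsafe@example.org",
           role = c("aut", "cre"))
Description: Tools for the tier-based specific absorption rate (SAR) safety
    assessment of custom-built radio-frequency transmit coil arrays.
    Quantifies the modeling uncertainty between simulated and measured
    field maps (B1+ magnitude and SAR, including SAR derived from MR
    thermometry time series), estimates intersubject variation from peak
    local SAR populations via gamma fits, propagates modeling,
    intersubject and power-monitoring uncertainties into a safety factor
    by the root-sum-of-squares rule, and derives per-channel average
    power limits for validation tiers 1-3. Includes seedable synthetic
    generators for multichannel phantom field maps, perturbed
    measurements, heating curves and peak-SAR populations so the whole
    pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
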