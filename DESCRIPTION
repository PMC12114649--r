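Package: adpgam
Title: Thermal-Time Phenology Models with Fall-Winter Temperature Residual
    Correction
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts spring phenological event dates (such as first
    flowering) from daily air-temperature records using three
    forcing-accumulation methods: accumulated degree days (ADD),
    accumulated days transferred to a standardized temperature (ADTS),
    and accumulated developmental progress (ADP) driven by linear,
    Arrhenius, Logan, or logistic temperature-dependent developmental-rate
    equations, with trapezoid fractional-day attainment, grid searches and
    Nelder-Mead RMSE minimization. The remaining prediction error is then
    modelled with generalized additive models of six fall and winter
    temperature summaries, including the Chilling Hours model with
    sine-interpolated hourly temperatures, a critical-low-temperature
    scan, drop-one contribution rates, and adjusted predictions. A seeded
    synthetic daily-climate and phenology generator supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
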