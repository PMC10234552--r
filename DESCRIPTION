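Package: roadfusion
Title: Hybrid Near-Road Air Quality Data Fusion, RAMP Bias Correction, and
    Exposure Equity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fuses a coarse gridded air-quality field (a chemical transport
    model) with a fine-scale near-road dispersion field at census-block
    resolution, corrects the fused field with the Regionalized Air quality
    Model Performance (RAMP) decile-bin calibration including a centre-out
    monotonicity safeguard, and converts the corrected exposures into
    attributable premature mortality and race-stratified exposure inequity
    ratios. Ships a seeded synthetic world generator (grid, roads, monitors,
    census blocks, true/biased/observed concentration fields) so the full
    pipeline is testable without national model runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
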