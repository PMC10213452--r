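Package: mearing
Title: Spike-Train Analysis for Ring-Shaped Neuronal Circuits on
    Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings of small,
    topologically constrained neuronal circuits grown on 60-electrode
    microelectrode arrays (MEAs), where four electrodes form one ring
    ("circuit") with a preferred clockwise direction of axon growth.
    Provides MAD-threshold spike detection on high-pass filtered traces,
    spontaneous-activity metrics (mean firing rate, active-electrode
    classification), a spike-pair directionality statistic on circuit
    rings, peri-stimulus stacked-raster construction with
    activity-inducing classification, magnesium dose-response curves
    with exponential decay-constant fits, the accompanying statistical
    tests (two-proportion Z, Mann-Whitney U with exact small-sample
    distribution, Mann-Kendall trend, Fisher's method), and a
    seed-reproducible synthetic-recording generator with known ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
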