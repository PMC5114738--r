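Package: srt1map
Title: Simulation and Analysis of Saturation-Recovery Myocardial T1 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bloch-equation simulation and quantitative analysis of cardiac
    T1 mapping at 3T. Builds heart-rate-driven acquisition schedules for
    MOLLI (5(3)3 and 4(1)3(1)2), SASHA and SAPPHIRE, simulates balanced-SSFP
    image series on a digital short-axis phantom cohort, estimates T1 maps by
    three-parameter relaxometry fits (with magnitude polarity restoration and
    Look-Locker correction), derives extracellular volume fraction and
    gadolinium concentration maps, aggregates AHA 16-segment statistics, and
    provides the statistical comparison machinery (repeated-measures ANOVA,
    Bartlett and paired variance tests, rank tests, observer agreement and
    intraclass correlation) used to compare T1-mapping methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    RNifti
Config/testthat/edition: 3
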