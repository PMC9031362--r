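Package: spheroscreen
Title: Monolayer and Spheroid High-Throughput Drug Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage analysis pipeline for high-content drug screens in
    monolayer (2D) and spheroid (3D) cancer cell cultures. Provides a
    synthetic screen simulator (plate layouts, ground-truth four-parameter
    log-logistic drug responses with planted spheroid-penetrance effects,
    noisy time-resolved live/dead counts), live/dead nuclei counting from
    two-channel fluorescence images, the time-resolved dead-fraction
    viability statistic, 4PL dose-response fitting, fit-independent observed
    activity area (AAobs) and AUC metrics, monolayer-vs-spheroid deltaAA
    residual analysis with a >=3-of-4-line elimination rule, and the full
    hit-prioritization funnel from primary screen to retained compounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
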