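Package: qpcrPlateVar
Title: Intra-Plate Measurement Variability of qPCR-Based GMO Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies and visualises the measurement variability hidden
    inside a single 96-well real-time PCR plate used for GMO quantification.
    Replicate wells for a transgene and a reference gene are recombined into
    thousands of seeded random combinations per replicate setting, converted
    to GMO percentages via per-gene standard curves, and summarised as
    frequency distributions with population statistics (population standard
    deviation, relative standard deviation, empirical skewness, a simplified
    chi-square test against the Gaussian normal distribution) and a 95
    percent class cut-off summary. Includes a synthetic-plate simulator with
    Poisson template sampling at low copy numbers for method evaluation
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'qpcrPlateVar-package.R'
    'AllClasses.R'
    'accessors.R'
    'calibration.R'
    'distribution-stats.R'
    'plate-layout.R'
    'plate-io.R'
    'quantification.R'
    'simulate.R'
    'resampling.R'
    'sweep.R'
    'report.R'
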