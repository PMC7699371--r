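Package: pmevalkit
Title: Laboratory Evaluation and Correction of Low-Cost Optical
    Particulate-Matter Monitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the laboratory evaluation of low-cost optical PM2.5
    monitors against a reference aerodynamic particle sizer, oriented at
    occupational exposure assessment. Provides a seeded simulator of
    exposure-chamber experiments (plateau and transient concentration
    profiles, material-, temperature-, humidity-, power-, pattern-, drift-
    and device-dependent sensor responses, high-concentration rollover),
    reference-instrument processing (size-bin counts to mass with density
    and dynamic-shape-factor correction, ISO 7708 respirable weighting,
    gravimetric calibration), screening of sensor rollover via local
    regression with pooled tenth-percentile concentration cutoffs,
    normalization-transform selection, mixed-effects correction models
    with a three-criterion variable-selection procedure (likelihood-ratio
    p-value, AIC decrease, mean-absolute-error decrease), and verification
    of accuracy as bin-wise relative uncertainty combining bias and
    precision against a 50 percent target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    MASS,
    car,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
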