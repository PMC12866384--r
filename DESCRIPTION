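Package: pypquant
Title: Quantitative Dynamic Tc-99m-Pyrophosphate SPECT/CT Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for absolute quantitation of dynamic and static
    Tc-99m-pyrophosphate SPECT/CT in suspected transthyretin cardiac
    amyloidosis (ATTR-CM): uniform-cylinder calibration to activity
    concentration, volume-of-interest statistics, SUVmean/SUVmax and
    percent-injected-dose-per-mL with decay and residual-dose correction,
    time-activity curve extraction, synthetic static imaging by
    duration-weighted frame averaging, blood-pool subtraction,
    blood-pool-threshold myocardial segmentation, and early-imaging
    diagnostic classification with performance and agreement statistics.
    Includes a seeded 4D digital thorax-phantom cohort generator whose
    tissue kinetics are anchored to published group time-activity values,
    so the full pipeline can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
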