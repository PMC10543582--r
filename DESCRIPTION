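Package: alpscombat
Title: Multisite Harmonization and Evaluation of the DTI-ALPS Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the diffusion-tensor image analysis along the
    perivascular space (DTI-ALPS) index from per-axis diffusivity maps and
    region-of-interest definitions, removes additive and multiplicative
    scanner/site/protocol effects with an empirical-Bayes location-scale
    (ComBat) model fitted after regressing out biological covariates, and
    evaluates harmonization performance with Cohen's d, Welch's t test,
    Pearson correlation, Type II ANOVA with partial eta squared, and
    noncentral-t power and sample-size calculations.  Includes a synthetic
    multisite cohort and toy diffusivity-volume generator so the full
    pipeline is testable without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse,
    withr
Config/testthat/edition: 3
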