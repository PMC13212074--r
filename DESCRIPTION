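Package: fognirs
Title: fNIRS Walking-Task Activation and Connectivity Analysis for
    Freezing of Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-wavelength functional near-infrared
    spectroscopy (fNIRS) recordings acquired during walking tasks that induce
    freezing of gait in Parkinson's disease. Converts raw light intensity to
    oxy- and deoxyhemoglobin concentration changes via the modified
    Beer-Lambert law, performs channel quality control, motion-artifact
    detection and cubic-spline correction, zero-phase Butterworth bandpass
    filtering, task-epoch block averaging with baseline correction, and
    channel-wise Pearson functional connectivity. Includes a synthetic cohort
    generator with a double-gamma hemodynamic response, physiological noise
    and latent connectivity structure, and a group-statistics layer
    (normality-gated two-sample tests, repeated-measures ANOVA with LSD
    post-hoc, Benjamini-Hochberg false discovery rate control, and gait
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
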