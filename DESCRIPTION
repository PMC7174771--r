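Package: fnirsbci
Title: Binary Communication Decoding from fNIRS Hemodynamic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for binary ("yes"/"no") communication
    experiments with functional near-infrared spectroscopy (fNIRS).
    Covers the sparse fronto-parietal optode montage and auditorily cued
    encoding paradigm, conversion of dual-wavelength raw light intensities
    to oxy-/deoxyhemoglobin concentration changes via the modified
    Beer-Lambert law, moving-average band filtering, channel-level quality
    control by the coefficient of variation, canonical double-gamma GLM
    fitting with contrast t-statistics, channel-of-interest selection,
    single- and multi-trial answer decoding with binomial empirical chance
    levels, multivariate pattern analysis with a linear support vector
    machine, permutation-based significance and majority voting, and a
    synthetic-participant simulator (hemodynamics, physiological noise,
    optical forward model) so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
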