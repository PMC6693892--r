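Package: quantsep
Title: Separating Neural Codes for Numerosity from Non-Numerical Quantities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissociating the contribution of numerosity from
    correlated non-numerical magnitudes (average item size, total field
    area, total surface area, density) in multivoxel fMRI activity
    patterns. Implements the factorial dot-array quantity design with
    collinearity diagnostics, cumulative-Gaussian psychometric fitting
    with JND extraction, a population encoding-model simulator with
    task-dependent attentional gain, leave-one-run-out linear support
    vector machine decoding, and multiple-regression representational
    similarity analysis with variance inflation factors, plus group-level
    inference (repeated-measures ANOVA with Greenhouse-Geisser
    correction, paired tests with effect sizes, linear trend across
    regions of interest).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
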