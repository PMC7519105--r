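Package: tactsurf
Title: Tactile Perception Analysis of Self-Affine Randomly Rough Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of self-affine randomly rough surfaces with independently
    controlled topographic structure and Hurst roughness exponent, together with
    the analysis chain used in psychophysics studies of their tactile and visual
    perception: scale-dependent roughness statistics (height-difference
    correlation, rms slope and curvature, Hurst estimation), a synthetic
    two-alternative forced-choice observer for triplet similarity judgements and
    fingertip friction trials, ordinal (non-metric) embedding of triplet
    decisions by likelihood maximization with cross-validation and bootstrap
    reliability, a curvature-plus-topography dissimilarity metric with salience
    fitting, and psychometric (Weibull) curve fitting with
    just-noticeable-difference extraction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
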