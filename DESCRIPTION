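Package: aptemporal
Title: Psychoacoustic Protocols, Scoring and Robust Inference for Absolute
    Pitch and Auditory Temporal Processing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studies relating absolute pitch to auditory temporal
    processing. Generates seeded test protocols for pitch identification
    (sine-tone and piano-tone variants), Gaps-in-Noise gap detection and
    clinical backward masking; scores trial-level response logs into the
    standard measures (correct response rate and mean absolute chroma
    deviation, gap detection percentage and threshold, backward-masking
    percent correct and threshold) with the 4-of-6 maintained-criterion
    threshold rule; classifies subjects into absolute-pitch groups via a
    binomial chance-level model; simulates parametric guess-lapse logistic
    observers and full two-group cohorts; and runs the inference chain of
    pooled t-tests with Hedges' g, Pearson correlations, bias-corrected and
    accelerated (BCa) bootstrap confidence intervals with CI-inversion
    p-values, Benjamini-Hochberg false-discovery-rate adjustment, and robust
    linear regression by Tukey-bisquare iteratively reweighted least squares
    with Cohen's f-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
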