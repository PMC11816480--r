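Package: vocalmatch
Title: Acoustic Scoring and Mixed-Model Inference for Vocal Imitation of
    Speech and Song
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how accurately an imitated utterance reproduces the
    pitch and timing of a model utterance, syllable by syllable. Reads
    Praat TextGrid and PitchTier annotations or flat syllable tables,
    computes seven per-trial metrics (absolute and relative pitch
    deviation in cents with octave-error folding, pitch contour and
    interval error counts, absolute and relative duration differences in
    milliseconds via interonset intervals, and time-error counts), and
    runs the accompanying inference protocol: Welch group comparisons
    with Cohen's d, effect-coded linear mixed-effects models with a
    deterministic random-structure reduction, estimated-marginal-means
    contrasts with Holm-Bonferroni correction, and Pearson correlations.
    A synthetic-study generator reproduces the two-group, two-condition
    imitation design with controllable ground-truth effects so every
    stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
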