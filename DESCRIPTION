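Package: padpref
Title: PAD Emotion Preference Scoring and ERP Feature Extraction
Version: 0.1.0
Authors@R: person("Dominic", "Hart", email = "dhart.neuro@posteo.net",
    role = c("aut", "cre"))
Description: Tools for affective-preference studies that combine
    semantic-differential emotion ratings with event-related potentials.
    Scores 12-item Pleasure-Arousal-Dominance (PAD) questionnaires, types
    responses into sign-octant emotion categories, identifies the nearest
    normative emotion by Euclidean proximity, computes a variance-free
    standardized mean difference, and classifies pleasure values into
    preference bands. A companion EEG chain provides zero-phase low-pass and
    notch filtering, epoch segmentation, baseline correction, mastoid
    re-referencing, amplitude-threshold artifact rejection, condition
    averaging, late-positive-potential peak extraction, and frontal-asymmetry
    valence classification. Synthetic generators for rater panels and
    lateralized evoked epochs make the full pipeline testable without any
    recorded data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
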