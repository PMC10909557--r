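Package: predtend
Title: Individual Prediction Tendency from Time-Resolved Neural Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying individual
    prediction tendency from multi-channel electrophysiological recordings.
    Generates entropy-modulated Markov stimulus sequences (ordered versus
    random transition regimes with stimulus omissions), simulates synthetic
    sensor-level recordings with controllable prestimulus pre-activation of
    expected stimuli, and recovers per-subject prediction tendency by
    time-resolved multiclass shrinkage linear discriminant decoding of
    matched self-repetition trials. Group-level inference uses cluster-based
    sign-flip permutation tests; cross-modal and split-half reliability are
    summarised with Pearson correlations, Cronbach's alpha and the
    Spearman-Brown formula.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
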