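Package: osnresponse
Title: Response Metrics, Tuning and Concentration Coding for Olfactory
    Sensory Neuron Input
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantifying olfactory sensory neuron (OSN)
    input to the olfactory bulb from glomerular calcium-imaging trial traces,
    voltage-clamp sweeps and behavioral assay tables. Computes trial-averaged
    dF/F response metrics with a baseline-SD responder criterion and blank
    subtraction, lifetime-sparseness odorant tuning, concentration-coding
    summaries (per-mouse amplitude means including zeros, ascending
    concentration-pair differences, top-concentration normalisation), a
    GCaMP-saturation frame-difference diagnostic, light-evoked EPSC kinetics
    (peak, 5-percent-of-peak onset latency, trial-to-trial jitter,
    monosynaptic classification), and scoring of buried-food, two-choice odor
    detection and habituation-dishabituation assays. Includes seeded
    synthetic-data generators with retained ground truth for all three
    modalities, emulating the mature-like (saturating) versus immature-like
    (graded) concentration-response contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
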