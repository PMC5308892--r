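Package: ensemblecode
Title: Ensemble Selectivity Analysis for Trace Eyeblink Conditioning
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how neural population codes
    for relational versus physical stimulus features evolve across
    learning in dual trace eyeblink conditioning. Provides eyelid-EMG
    conditioned-response scoring via the Hilbert envelope, learning-stage
    segmentation from daily conditioned-response rates, unit quality
    control and binned firing-rate tensors, population-vector similarity
    with permutation inference, permutation-calibrated support-vector-machine
    population decoding, and single-neuron selectivity statistics
    (differentiation index, mutual information with permutation nulls,
    neuron categorization). A synthetic-data generator emulates the
    two-epoch, four-condition trial structure and the neural coding
    classes the analyses assume, so the full pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
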