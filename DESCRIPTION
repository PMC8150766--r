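Package: ieegfuse
Title: Multi-Branch Fusion Classification of Epileptogenic Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies epileptogenic (ES) versus non-epileptogenic (NES)
    intracranial EEG segments with a multi-branch fusion model: a 70-feature
    multi-domain extractor (time, frequency, EMD fuzzy-entropy, and ten
    entropy/fractal measures per DWT sub-band) feeding a bidirectional
    LSTM with additive attention, a raw-signal one-dimensional convolutional
    branch, and a fused 256-dimensional classifier head. Includes readers and
    writers for two-column and one-column ASCII segment dialects and EDF
    sessions, a sliding-window resampling procedure that balances minority
    epileptogenic leads against majority leads, a synthetic iEEG generator for
    reproducible end-to-end testing, and an intra-/cross-subject evaluation
    harness reporting accuracy, sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
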