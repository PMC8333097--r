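Package: sincbird
Title: Raw-Waveform Bird Call Classification with Learnable Sinc Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of bird vocalizations directly from raw audio
    waveforms. The first convolutional layer is a bank of band-pass filters
    parameterized only by their low and high cut-off frequencies through the
    cardinal-sine (sinc) function, initialized on the mel scale and learned by
    gradient descent; a conventional convolutional and fully-connected stack
    follows, emitting per-frame log-posteriors that are averaged over a sound
    event to vote for its class. The package includes a synthetic labeled
    soundscape generator emulating richly annotated field-recording datasets
    (imbalanced call classes, overlapping vocalizations, nuisance tags,
    background noise), rich-label parsing and segment cropping, train/test
    list construction, a CPU training loop, and a multi-metric evaluation
    suite (accuracy, one-vs-rest ROC AUC, weighted precision/recall/F1,
    top-k accuracy, proportion confusion matrix, overlap credit analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
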