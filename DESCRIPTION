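Package: promcnn
Title: Convolutional Neural Network Recognition of Promoter Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and applies convolutional neural network classifiers for
    transcription-start-site-anchored promoter windows. Provides FASTA input
    and one-hot encoding of fixed-length DNA windows, a declarative
    architecture language for one- to multi-layer convolutional models with
    max-pooling and a dense ReLU layer, training with the Adam optimizer and
    validation-based epoch selection, sensitivity/specificity/accuracy and
    the Matthews-style correlation coefficient, a random-substitution
    sliding-window procedure that localizes positionally conserved promoter
    elements from a trained model, per-position information-content
    (sequence-logo) profiles, and a synthetic corpus generator that plants
    position-weight-matrix motifs at TSS-relative offsets for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
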