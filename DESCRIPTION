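Package: sfebci
Title: Asynchronous Artifact-Enhanced EEG Control Decoding with Slight Facial Expressions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming decoder for an asynchronous electroencephalogram (EEG)
    control interface driven by slight facial expressions. Implements the
    four-step pipeline (temporal-energy screening, common-spatial-pattern plus
    support-vector-machine switch-on detection, a Conv1D-GRU nine-class window
    classifier, and consistency-based validity judgment with a non-control /
    in-control state machine), together with multivariate-autoregressive
    effective-connectivity analysis (generalized orthogonalized partial
    directed coherence), sample-entropy based artifact-component auditing with
    FastICA and empirical mode decomposition, a synthetic-EEG session
    generator for end-to-end testing, virtual device adapters with stepping
    control, and reporting utilities (placement intersection-over-union,
    aggregate statistics, time logs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
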