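Package: lfpdecode
Title: Layer- and Band-Specific Decoding of Tone Frequency from Multielectrode LFP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding sound frequency from sustained multielectrode
    local field potential (LFP) recordings of the auditory cortex under
    burst-suppression anesthesia. Implements burst-epoch screening on 100-ms
    standard-deviation criteria, band-specific power and phase-locking-value
    (PLV) feature extraction from one-second non-burst windows, sparse
    multinomial logistic regression with automatic relevance determination for
    five-choice and two-choice frequency decoding under periodic and
    rolling-window cross-validation, and paired pre/post-intervention accuracy
    comparison with an exact Wilcoxon signed-rank test. A synthetic tonotopic
    LFP generator with known ground truth (spatial gain foci, controllable
    inter-site phase coupling, pink-noise floor, global burst events) makes
    every stage testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
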