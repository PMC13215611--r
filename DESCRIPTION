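Package: dualseq
Title: Trial-Level Decoding of Cognitive Operation Sequences in Dual-Task EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes multichannel dual-task EEG epochs into probabilistic
    onsets of latent cognitive operations (Encoding, Central, Response) using
    an EM algorithm with gamma-distributed stage durations, trains a causal
    spatiotemporal sequence labeler on the resulting soft labels with a
    Kullback-Leibler loss, decodes per-trial cross-task operation sequences
    with uncertainty via constrained posterior sampling, and links decoded
    sequences to reaction time and accuracy through multiple imputation with
    Rubin's-rules pooling. Includes a synthetic dual-task generator with known
    ground truth for end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
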