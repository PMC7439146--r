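Package: sleephmm
Title: Unsupervised Personalized Sleep/Wake Scoring from Wearable Heart
    Rate and Step Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies sleep and wake minutes from consumer wearable
    streams (1-minute heart rate, 15-minute step counts) without any
    labelled training data. A two-state hidden Markov model with
    bivariate-Gaussian emissions (joint or conditionally independent) is
    fitted per person by the Baum-Welch algorithm with a missing-data
    likelihood, decoded by the Viterbi algorithm, and post-processed with
    Webster rescoring rules. Includes nonwear-day screening, step-count
    downscaling, AIC/BIC model selection, ordinary normal pseudo-residual
    diagnostics, per-day model fits with weekday/weekend comparisons, and
    a device-realistic synthetic data generator so the full pipeline can
    be exercised without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
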