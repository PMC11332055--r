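Package: qcla
Title: Question-Based Computational Language Assessment of Emotional States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether open-ended descriptive-word responses,
    quantified as word embeddings, categorize emotional-state narratives
    (harmony, satisfaction, depression, anxiety) more accurately than
    standardized rating scales (PHQ-9, GAD-7, SWLS, HILS). Provides a seeded
    synthetic-data generator with emotion lexicons and a latent-Gaussian
    copula for correlated Likert scale scores, deterministic word-response
    cleaning, a pluggable word-embedding encoder (seeded mock encoder and an
    offline embedding-cache adapter), narrative-grouped 10-fold
    cross-validated multinomial classification with singular-value-
    decomposition compression and inner dimension-ladder selection, the
    semantic t-test word contrast for word-cloud export, and the comparative
    statistics used to contrast language measures with rating scales:
    two-proportion chi-square with phi effect size, per-class accuracy and
    precision, inter-rater agreement, and Fisher r-to-z comparison of matched
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
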