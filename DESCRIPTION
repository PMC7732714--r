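Package: redsup
Title: Distant Supervision for Detecting Suicidality and Opioid Misuse in
    Social Media Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for detecting posts that combine
    suicidal ideation with opioid misuse in Reddit-style forum corpora.
    Classifiers are trained with distant supervision, using the community a
    post was filed under as its label (suicide-watch versus control
    communities; opioid communities versus depression), and then transferred
    out of context to score posts from a held-out community group.  The
    package implements the full chain: a synthetic corpus generator with
    known latent risk flags and simulated noisy annotators, text cleaning
    and fixed-length integer encoding, TF-IDF and word/character embedding
    features, seven classifier families (logistic regression, random forest,
    support vector machine, a fastText-style averaged-embedding network, an
    LSTM, an attention-based bidirectional LSTM, and a convolutional text
    classifier), keyword-stratified evaluation sampling, majority-rule
    annotation aggregation, label-ratio sensitivity curves, an adaptive
    boosting ensemble over weak-learner scores, and bigram-phrase embedding
    queries over predicted-positive posts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    ranger,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
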