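Package: mihmm
Title: Hidden Markov Modelling of Motivational Dynamics in Counseling
    Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating motivational-interviewing session quality
    from per-utterance motivational strength scores. Client score sequences
    are modelled with three-state hidden Markov models fitted by Baum-Welch
    across multiple sequences and decoded with Viterbi; group-level
    transition matrices are compared with a Frobenius-norm permutation
    test; and subgroup-level transition features predict session quality
    via ridge-regularized logistic regression under leave-one-out
    cross-validation. Includes a deterministic lexicon scorer as a
    pluggable stand-in for model-based utterance scoring, inter-rater
    agreement statistics (Cohen's and Fleiss' kappa), a seeded synthetic
    session generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
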