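Package: swarmrec
Title: Swarm-Intelligence Feature Selection and Top-N Recommendation for
    Behaviour-Pattern Screening
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating hybrid recommender pipelines for
    behaviour-pattern screening in digital mental health. Implements a software
    emulation of systolic-tree frequent-pattern mining with a brute-force Apriori
    oracle, TF-IDF text featurization with a built-in Porter stemmer, the River
    Formation Dynamics (RFD) graph metaheuristic, inertia-weight global-best
    Particle Swarm Optimization (PSO), a hybrid RFD-PSO wrapper feature selector,
    user-based collaborative filtering with precision/recall at N evaluation, and
    synthetic-data generators (ratings, transactions, labelled corpora,
    actigraphy) with planted, recoverable structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
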