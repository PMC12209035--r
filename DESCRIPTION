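Package: semfluency
Title: Automatic Semantic Clustering and Scoring of Verbal Fluency Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for objective, reproducible scoring of semantic verbal
    fluency tests (VFTs). Semantic clusters in a sequence of timed word
    responses are detected automatically from a topic-probability lexicon:
    two consecutive responses are linked when both exceed a probability
    criterion on a shared latent topic, and linked pairs chain into maximal
    runs (Markovian clustering). The package builds such lexicons from a
    pre-tokenized corpus with a collapsed Gibbs sampler for latent Dirichlet
    allocation, derives the clustering criterion from a lexicon, computes
    the standard measure battery (mean cluster size, switches,
    within-/out-of-cluster response intervals, word-frequency-decay slope,
    repetition and intrusion counts), quantifies agreement between
    automatic and manual clusterings with Cohen's kappa, and ships
    synthetic generators (lexicons, response sequences with planted
    cluster structure, planted-topic corpora) so the whole pipeline is
    testable end to end without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stringi,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
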