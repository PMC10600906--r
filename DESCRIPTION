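Package: sixmApred
Title: Cross-Species N6-Methyladenosine Site Prediction from Sequence Encodings
Version: 0.1.0
Authors@R: person("sixmApred", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Predicts N6-methyladenosine (6mA) modification sites in fixed-length
    DNA or RNA windows centred on an adenine. Implements five nucleotide
    encoding families (one-hot, Kmer, ENAC, CKSNAP, NCP) over a fifteen-scheme
    parameter grid, logistic-regression and random-forest classifiers with
    default and tuned hyperparameter configurations, stratified five-fold
    cross-validated evaluation (accuracy, sensitivity, specificity, Matthews
    correlation coefficient, AUC), cross-species transfer testing, a seeded
    synthetic benchmark generator, and a command-line pipeline tying the pieces
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
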