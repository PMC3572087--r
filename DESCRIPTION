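Package: glutapred
Title: Sequence-Based Prediction of Protein S-Glutathionylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting cysteine S-glutathionylation sites from
    protein sequence alone. Extracts fixed-width peptide windows centered on
    cysteines, encodes them under eight sequence descriptor schemes (amino
    acid, reduced-alphabet, dipeptide and tripeptide compositions,
    reversal-merged tripeptides, one-hot binary profiles, bi-profile Bayes
    position frequencies, and summed physicochemical properties), ranks
    features by a two-sample Student's t-test, and evaluates support vector
    machine, k-nearest-neighbor and random forest classifiers under
    leakage-safe stratified cross-validation with a full confusion-matrix and
    ROC metric suite. Includes a PROSITE-dialect motif scanner and a
    synthetic-data generator with plantable position-specific flank signal so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    seqinr,
    e1071,
    randomForest,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
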