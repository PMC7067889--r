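Package: mc4deep
Title: Deep Hybrid Classifier for DNA N4-Methylcytosine Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA N4-methylcytosine (4mC) sites from fixed-length
    cytosine-centred sequence windows. Implements eight classical sequence
    feature encodings (binary/k-mer frequency, dinucleotide profiles,
    nearest-neighbour label features, physicochemical dinucleotide scales,
    mutual-information composition terms, pseudo dinucleotide composition,
    EIIP-weighted trinucleotide frequencies and ring/hydrogen/chemical-group
    codes), a per-encoding convolutional + bidirectional LSTM feature
    extractor that emits one sigmoid probability per encoding, an iterative
    probability-stacking ensemble of six classical learners, and a small
    fully connected network producing the final site calls, together with
    standard binary-classification metrics (SN, SP, ACC, MCC, AUC), a seeded
    synthetic benchmark generator and an end-to-end cross-validated pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    e1071,
    ranger,
    rpart,
    class,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Collate: 
    'RcppExports.R'
    'metrics.R'
    'sequence_io.R'
    'encoders.R'
    'network.R'
    'stacking.R'
    'final_net.R'
    'mc4deep-package.R'
    'pipeline.R'
    'synthetic.R'
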