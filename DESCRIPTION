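Package: sixmA
Title: N6-Methyladenosine Site Prediction from Moment-Based Sequence Encodings and Ensemble Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts N6-methyladenosine (6mA) sites in RNA from fixed 41-nt
    sequence windows centred on a candidate adenosine. Each window is encoded
    as a 522-dimensional descriptor built from k-mer frequency vectors,
    accumulative position-incidence vectors (AAPIV/RAAPIV), position-relative
    incidence matrices (PRIM/RPRIM) and integer-encoded sequence matrices,
    with raw, central and discrete Hahn moments used for dimensionality
    reduction of the matrix blocks. Stacking, bagging and boosting ensembles
    are trained on the encoded features and assessed by an independent
    train/test split and stratified k-fold cross-validation with
    sensitivity, specificity, accuracy, MCC, F1 and AUROC. Includes a seeded
    synthetic-window generator with a configurable planted positional
    composition bias, FASTA/TSV input, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    nnet,
    ranger,
    randomForest,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
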