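Package: pathburden
Title: Pathway-Threshold Disease Models and Machine-Learning Benchmarks
    for Case/Control Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Abstract pathway-threshold ("toy") disease models over 0/1/2
    risk-allele dosage genotypes, and the simulation machinery to study how
    disease structure affects machine-learning risk prediction.  Provides
    four model variants (simple, weighted, overlap, subtype) with a
    deterministic case/control oracle; calibrated synthetic case/control
    core genotype generation with nearest-neighbour imputation;
    marginal-preserving "rectangle shuffle" population expansion; data
    perturbations (missing predictive alleles, surplus irrelevant alleles,
    case-to-control label noise); a classifier panel (naive Bayes, logistic
    regression, decision tree, random forest, single-hidden-layer neural
    network) scored by rank-based AUC with replicate experiments and Welch
    tests; and reverse-engineering of pathway structure from neural-network
    first-layer weights via a 2-D t-SNE embedding and a pathway-purity
    score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    nnet,
    randomForest,
    Rcpp,
    rpart,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
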