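Package: litsel
Title: Literature-Mined Feature Selection for Anticancer Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and benchmarking text-mining-based gene
    feature sets for pharmacogenomic machine learning. Implements a
    Genie-style literature scorer (naive Bayes topic classification of
    abstracts, per-gene Fisher enrichment, FDR-ranked gene lists), nine
    feature-selection strategies (text-mining, variance, correlation,
    landmark gene lists, MRMR, genetic algorithm, recursive feature
    elimination), a repeated cross-validation and cross-domain benchmark
    over elastic net, random forest and a small multilayer perceptron,
    univariate biomarker analysis, and survival-based validation via
    Kaplan-Meier curves and the log-rank test. Seeded synthetic-data
    generators produce literature corpora with planted gene-drug
    associations and paired pharmacogenomic domains with known sparse
    signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
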