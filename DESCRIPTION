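Package: wbfs
Title: Weight-Based Information-Theoretic Feature Selection for Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Greedy forward filter feature selection for discretized tabular
    omics data. Implements a weight-based selection criterion (WBFS) that
    scores each candidate feature by its conditional mutual information with
    the class, weighted by the interaction gain it confers on features already
    selected, together with the classical information-theoretic baselines
    (MIM, MIFS, mRMR, CIFE, CONDRED, DISR) behind a single interface.
    Includes plug-in entropy and mutual-information estimators on integer
    codes, equal-width discretization, missing-value preprocessing for
    protein-expression matrices, a stratified cross-validation benchmarking
    protocol with Win/Tie/Loss comparison, a planted-structure synthetic data
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    class,
    e1071,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
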