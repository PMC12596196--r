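Package: rmodulon
Title: Robust Independent Component Analysis of Bacterial Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers independently modulated gene sets (iModulons) from bulk
    RNA-seq compendia by robust independent component analysis: an ensemble of
    randomized FastICA runs is consensus-clustered with DBSCAN under the
    1 - |Pearson rho| distance, gene membership is assigned by iterative
    D'Agostino K-squared outlier thresholding, member sets are scored against a
    known transcriptional regulatory network with Fisher's exact test and
    Benjamini-Hochberg FDR, and condition-dependent module activities are
    clustered and compared. Includes a synthetic-compendium generator with
    planted modules and a planted regulatory network so every stage is
    verifiable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
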