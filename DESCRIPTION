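Package: sanderpop
Title: Hybrid Ancestry, Population Structure and Divergence Dating for
    Sauger-Walleye Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybridization and dam-induced population
    divergence in riverine fishes, built around the sauger (Sander
    canadensis) x walleye (S. vitreus) system. Implements admixture
    proportion (q) and interspecific ancestry (Q) estimation by
    expectation-maximisation with threshold-based hybrid classification
    (F1, F2, backcross), discriminant-analysis screening for sex-linked
    loci, the Reich-Patterson FST estimator with locus bootstrap,
    genotype-covariance PCA, per-site diversity statistics, isolation by
    distance along river networks with Mantel tests, and two-population
    divergence-time inference from the folded joint site-frequency
    spectrum using a discrete Wright-Fisher expected-spectrum backend
    with composite-likelihood fitting, likelihood-ratio tests and block
    bootstrap. A synthetic-data module generates parental panels, hybrid
    crosses, population splits, stepping-stone rivers and sex-linked
    blocks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    nloptr,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
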