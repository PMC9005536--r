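Package: rumenGS
Title: Host-Genomic Analysis of Rumen Microbiome Traits and Microbiome-Driven Genomic Selection for Methane
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating host-genomic control of rumen microbial
    abundances and their genomic relationship with methane emissions, and for
    evaluating microbiome-driven genomic selection. Includes compositional
    data handling (relative abundance, core-feature filtering,
    Bayesian-multiplicative zero replacement, additive and centred log-ratio
    transforms with reference diagnostics), SNP quality control and the
    VanRaden genomic relationship matrix, Gibbs-sampler GBLUP animal models
    (univariate, bivariate and multi-trait with missing records), posterior
    summaries and convergence diagnostics, DIC and Bayes-factor model
    comparison, correlated response to selection, covariance assembly with
    bending, genomic prediction scenarios, response-to-selection
    distributions, and Markov clustering of deregressed-GEBV co-abundance
    networks. A simulator generates genotypes, multi-trait phenotypes and
    compositional microbiome count tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
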