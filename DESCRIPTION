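Package: erpower
Title: Power Analysis for Evolve-and-Resequence Experiments Under
    Truncating Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Individual-based forward simulation of replicated
    evolve-and-resequence (E&R) experiments on a quantitative trait
    under temporally varying truncating selection, together with the
    statistical machinery to evaluate their power to detect causative
    loci: synthetic founder haplotype pools with a neutral-like site
    frequency spectrum, window-based recombination maps, additive trait
    architectures with gamma-distributed effects, Cochran-Mantel-Haenszel
    scoring of replicated allele-frequency changes, ROC/partial-AUC power
    evaluation, hitchhiking and drift diagnostics, phenotypic response
    analysis, and a single-marker association (GWAS) benchmark on nested
    cohorts drawn from the same founders.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
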