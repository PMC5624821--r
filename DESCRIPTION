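Package: relkit
Title: Graphical Relatedness Analysis from Allele Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and identifying family relationships between
    diploid individuals from co-dominant marker data. Computes pairwise
    identity-by-state (IBS) sharing statistics together with the exact
    attainable domain of the mean/standard-deviation plot, estimates
    Cotterman identity-by-descent (IBD) coefficients by maximum likelihood
    with an EM algorithm, expresses both kinds of sharing probabilities in
    compositional coordinates (ternary diagrams and isometric log-ratio
    plots), and quantifies the uncertainty of each standard relationship by
    convex hulls of artificial relative pairs generated by Mendelian gene
    dropping. Reads PLINK PED/MAP and a simple tabular genotype dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
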