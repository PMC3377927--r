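Package: epiqtl
Title: Mapping Epistatic Multiallelic QTL in Full-Sib Families of Outbred Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Interval mapping of pairs of interacting quantitative trait loci
    (QTL) in a full-sib family derived from two outbred, heterozygous parents.
    Each QTL segregates four genotypes (alleles 1/2 from one parent, 3/4 from
    the other); the two-locus genotypic values are decomposed into an overall
    mean, parent-specific additive effects, dominance, and nine epistatic
    components via an orthogonal +/-1 design matrix. Fitting uses a
    16-component normal mixture maximized by EM with conditional QTL-genotype
    probabilities derived from flanking markers under a Haldane (no
    interference) gamete model. Includes a two-dimensional likelihood-ratio
    genome scan, permutation thresholds, constrained-EM tests for each of the
    15 genetic effects, and a full-sib family simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
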