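Package: palmpop
Title: Population Structure and Allelic Differentiation from
    Genotyping-by-Sequencing Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Survey population structure in clonally propagated crops from
    multi-sample variant calls. Implements genotype-likelihood and coverage
    filtering of biallelic SNVs, a Gibbs-sampled admixture model with
    replicate label alignment and Evanno delta-K model choice, purity-based
    population assignment, principal components ordination of genotype
    codes, and two-population differentiation statistics: private alleles,
    Weir-Cockerham Fst (mean and ratio-of-sums summaries), per-site Fisher
    exact allele-frequency scans with Bonferroni correction, fixed
    differences, linkage-group enrichment on artificial chromosomes built
    from a genetic map, and outgroup polarization of region-segregating
    sites. Includes a calibrated two-population simulator (Balding-Nichols
    divergence) with per-call depth, genotype-likelihood noise and duplicate
    samples for end-to-end validation, plus concatenated-SNP alignment
    export for external phylogenetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
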