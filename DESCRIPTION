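Package: pleiocfdr
Title: Cross-Trait Pleiotropy Analysis with Conditional FDR and Mendelian
    Randomization for CpG-SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-trait analysis of GWAS summary statistics with a
    focus on potentially functional CpG-SNPs. Classifies CpG-SNPs from flanking
    sequence context, merges and harmonizes two summary-statistics sets,
    performs windowed LD pruning and p-value clumping against a genotype
    reference panel, computes stratified conditional Q-Q and inflation-corrected
    fold-enrichment curves, estimates per-SNP conditional and conjunction false
    discovery rates (cFDR/ccFDR), and runs a bi-directional two-sample
    Mendelian randomization suite (IVW, MR-Egger, weighted median, simple and
    weighted mode). Includes a seeded synthetic summary-statistics generator
    with known pleiotropic architecture for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
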