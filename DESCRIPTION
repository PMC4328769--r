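Package: radscape
Title: Phylogeographic Analysis of RAD-Seq and Mitochondrial Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing phylogeographic hypotheses in disjunct montane
    species from individually genotyped RAD-seq SNP catalogs and mitochondrial
    haplotype alignments. Provides catalog filtering (depth masking, biallelic
    and SNP-count rules, per-locus presence thresholds), diversity and
    differentiation statistics (heterozygosity, haplotype and nucleotide
    diversity, Tajima's D, Weir-Cockerham and Hudson F_ST), locus-subsampling
    saturation diagnostics for heterozygosity and for neighbor-joining tree
    topology against a constraint tree, statistical-parsimony haplotype
    networks with a probability-based connection limit, strict-clock
    divergence dating, and approximate Bayesian computation model choice
    among competing divergence scenarios (rejection and multinomial logistic
    regression) driven by a built-in coalescent simulator with finite-sites
    mutation, read-depth and missingness models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    igraph,
    nnet,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
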