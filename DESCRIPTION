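Package: alphasat
Title: Simulation and Analysis of Alpha-Satellite Centromere Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for the computational stages of
    telomere-to-telomere centromere studies. Generates synthetic
    alpha-satellite centromeres with full ground truth (layered
    higher-order-repeat arrays, haplotype pairs evolved under a neutral
    coalescent model, ultra-long error-bearing reads, CpG methylation and
    CENP-A-like enrichment tracks), and provides the analysis stages those
    truths exercise: singly-unique-k-mer (SUNK) scaffolding of fragmented
    contigs, k-mer based consensus quality (QV) estimation, windowed
    sequence-identity analysis, monomer decomposition and higher-order
    repeat annotation with self-identity heatmaps, centromere dip region
    (CDR) detection from methylation plus CENP-A enrichment, Tamura-Nei
    divergence and per-generation mutation-rate estimation, and
    coalescent-calibrated dating of newly emerged repeat variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    ape,
    phangorn,
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
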