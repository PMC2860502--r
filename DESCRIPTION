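Package: textileplot
Title: Textile Plots for Multi-SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Visualization of linkage disequilibrium (LD) in unphased
    multi-SNP genotype data with the textile plot, a parallel-coordinate
    display whose axis locations and scales are chosen by a constrained
    least-squares horizontalization criterion solved as a generalized
    eigenproblem. Includes genotype readers (VCF, PLINK ped/map, TSV),
    indicator/contrast encoding with missing-data weights, pairwise LD
    statistics (D, D', r-squared) with a two-locus EM haplotype frequency
    estimator, homozygous-stretch haplotype frequency approximation,
    Hardy-Weinberg genotype simulation from haplotype pools, axis
    reordering by ordered single end-linkage clustering, and a
    deterministic SVG renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ape,
    xml2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
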