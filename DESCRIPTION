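Package: breedmap
Title: Breed-Structured Mapping of Canine Compulsive-Disorder Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for mapping complex-trait loci in dog breeds:
    intensity-based SNP genotype calling (per-chip quantile normalization,
    SNP-wise principal components, EM clustering with a t-distribution
    mixture), case/control allelic association with LD clumping into
    candidate regions, breed fixation and reduced-variability scans,
    interval-based permutation gene-set enrichment, case-only rare-variant
    gene burden with constrained-element restriction, and breed-group
    allele-frequency contrast statistics. Includes a breed-structured
    synthetic-data generator (Balding-Nichols allele frequencies, planted
    associated loci, fixed regions and variant burdens) so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    fgsea,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
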