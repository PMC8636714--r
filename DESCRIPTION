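Package: gourdcore
Title: Core SNP Marker Panels, Fingerprinting and Core Collections for
    Germplasm Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying small, chromosome-balanced core
    panels of biallelic SNP markers in germplasm collections, modelled on
    KASP-style genotyping workflows. Computes per-locus diversity statistics
    (minor allele frequency, observed heterozygosity, gene diversity,
    Botstein polymorphism information content), selects a minimal
    discriminating marker panel by greedy pair resolution under per-chromosome
    quotas with saturation curves, builds multilocus SNP fingerprints with
    barcode payloads for duplicate detection, variety authentication and
    hybrid seed purity, and selects coverage-constrained core collections
    evaluated with modified Rogers and Cavalli-Sforza-Edwards distances.
    Includes seeded simulators for structured inbred panels
    (Balding-Nichols model) and MAGIC-style recombinant inbred populations.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
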