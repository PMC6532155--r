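Package: snpanel
Title: Design and Evaluation of Medium-Density SNP Genotyping Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing medium-density SNP genotyping arrays for
    livestock from multi-population resequencing data, modelled on the design
    of a 55K chicken array. Implements candidate marker screening (minor
    allele frequency and allele-frequency differentials between local breeds
    and commercial lines, association-study top fractions, consequence-ranked
    gene-based capping, Fst quantile filters), a window-partitioned
    even-placement algorithm that retains at most two markers per 22 kb
    window by minimising a positional variance criterion, and an evaluation
    suite for the finished panel: genotype quality control with an exact
    Hardy-Weinberg test, identity-by-state distances with classical
    multidimensional scaling, and linkage-disequilibrium decay profiles.
    Seeded generators provide synthetic pooled allele frequencies and
    genotype matrices with controlled differentiation, linkage and
    missingness so every step can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
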