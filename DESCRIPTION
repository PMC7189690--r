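Package: bbmosaic
Title: Beta-Binomial Mixture Detection of Mosaic Variants from Trio Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects post-zygotic (mosaic) single-nucleotide variants among
    apparent de novo mutations in proband-parent trio exome data. Alternate
    allele read counts are modelled with a beta-binomial distribution whose
    overdispersion is estimated from depth-binned maximum likelihood; an
    expectation-maximization mixture estimates the prior mosaic fraction
    directly from the data; per-site likelihood ratios and posterior odds
    provide calls with an analytic false discovery bound. Includes the full
    candidate-filter cascade (de novo support, rarity and region exclusion,
    PV4 and strand bias, cohort-level recurrence/outlier/cluster rules, an
    FDR-based minimum alternate read threshold), depth-calibrated detection
    power with inverse-power adjustment of observed mosaic counts, mutation
    spectrum and variant allele fraction group comparisons, amplicon
    validation classification, and a seeded synthetic trio-cohort simulator
    with truth labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
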