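Package: xbias
Title: Chromosomal Distribution of Sex-Biased Gene Expression and
    Dosage-Compensation Proximity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how male- and female-biased genes are
    distributed between the X chromosome and the autosomes across
    Drosophila tissues, and how sex-biased expression relates to the
    distance from binding sites of the dosage compensation complex (DCC).
    Provides readers for GFF3 gene annotations and BED binding-site
    intervals, FDR-based and nominal-p sex-bias classification of
    differential-expression tables, observed/expected X-linkage enrichment
    with Fisher exact tests, minimum-distance and high-affinity-site (HAS)
    proximity analyses, the tau tissue-specificity index, RPKM and
    X:autosome dosage summaries, gene-age and gene-set overlap statistics,
    and a fully specified negative-binomial count simulator with exposed
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
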