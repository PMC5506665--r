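Package: chipscale
Title: Spike-In-Free Depth Calibration for ChIP-Seq with Global Signal Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and quantifies global loss of a broad histone mark
    (e.g. H3K9me2) between two ChIP-seq conditions without spike-in
    chromatin. Coverage is aggregated in fixed genomic bins; a
    between-condition rescaling factor is estimated from the
    extreme-coverage alignment-artifact bins shared by IP and input
    libraries, validated against the input libraries, and applied before
    genome-wide, promoter-level (TSS +/- 2 kb) and enriched-domain
    comparisons. Includes a synthetic ChIP-seq experiment generator with a
    ground-truth record for end-to-end validation, and summary statistics
    for histone-PTM relative-abundance tables (log2 ratios, Welch t-tests).
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
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
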