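Package: selscape
Title: Dual-Timescale Selection Scans and Disordered-Region Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting signatures of natural selection on a gene set
    at two timescales. A multi-population genome scan computes windowed
    site-frequency-spectrum statistics (nucleotide diversity, Watterson's
    theta, Fay and Wu's theta-H, Tajima's D, unnormalized Fay and Wu's H) from
    polarized variant data, ranks them per population, assigns minimum ranks
    to genes and calls cross-population concurrent outliers, with a resampled
    background comparison of nucleotide diversity. A protein-level layer
    consensus-calls positively selected sites from per-method site tables,
    builds ortholog-consensus intrinsically disordered regions (IDRs),
    computes IDR sequence descriptors (FCR, NCPR, SHD), and runs
    length-weighted binomial enrichment and group-comparison statistics.
    Includes a neutral coalescent simulator with a selective-sweep distortion
    and an ortholog-proteome generator so every stage can be calibrated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
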