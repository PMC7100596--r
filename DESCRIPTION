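Package: lfrclust
Title: Reference-Free Clustering of Linked-Read Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters co-barcoded (linked-read) sequencing barcodes that
    originate from the same genomic region without a reference genome or
    alignments. Barcodes are profiled by their unique k-mers (k-mers whose
    genome-wide frequency is consistent with single-copy sequence), a sparse
    barcode-barcode similarity graph is built in linear time through an
    inverted k-mer index, clusters are grown from seed barcodes by iterative
    enrichment under a k-mer frequency-diversity selection model, mixed
    clusters are split with Markov clustering, and low-depth non-target reads
    are removed from finished clusters. Includes a linked-read simulator with
    exact ground truth (stLFR-like and 10X-like presets) and a
    precision/recall evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
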