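Package: kmerscaff
Title: Alignment-Free Genome Scaffolding with Linked-Read Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scaffolds draft genome assemblies using barcoded linked reads
    (10x Genomics Chromium style) without read alignment. Reads are assigned
    to contig end regions by exact canonical k-mer matching, contig ends that
    share barcodes are linked into a scaffold graph, relative orientations
    are resolved with an exact binomial test, and gap sizes are estimated
    from the Jaccard index of end barcode sets via an empirical intra-contig
    model. Includes a linked-read simulator with full ground truth, a
    reciprocal-best path builder that merges contigs into scaffold sequences,
    and evaluation utilities for synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
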