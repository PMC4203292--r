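Package: barcodeDelim
Title: Distance, Tree and Character Based Species Delimitation from DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative species delimitation from aligned DNA
    barcode sequences (typically the 5' COI fragment). Implements
    Kimura two-parameter (K2P) pairwise distances with transition and
    transversion proportions, intraspecific and interspecific distance
    summaries and barcoding-gap detection, neighbor-joining trees with
    bootstrap supports and per-taxon monophyly assessment, automatic
    barcode-gap partitioning into candidate species (initial and
    recursive partitions over a grid of prior intraspecific
    divergences), tree-free discovery of single-nucleotide diagnostic
    characters, and identification success rates with Wald binomial
    confidence intervals. Includes a calibrated K80 sequence simulator
    with planted species clusters and diagnostic sites so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
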