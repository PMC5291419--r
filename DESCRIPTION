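Package: promscan
Title: Promoter Scanning for Transcription Factor Binding Sites by
    Position Weight Matrix Dissimilarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans transcription-start-site anchored promoter windows for
    transcription factor binding sites using position weight matrices
    (JASPAR and TRANSFAC text formats), scoring every window with a
    min-max normalised matching score and its complement, the
    dissimilarity rate (0% at the matrix consensus). Includes promoter
    extraction from genome FASTA plus BED6/GFF3 annotations with correct
    strand handling, threshold classification of candidate genes,
    gene-list overlaps, sequence-logo information content, and the
    quantitative verification toolkit used downstream of such screens:
    efficiency-corrected qPCR relative quantities with log2 one-sample
    t-tests, ChIP-qPCR percent input, Benjamini-Hochberg FDR gating and
    fold-change binning of expression tables. Seeded synthetic-fixture
    generators (planted-motif promoters, replicate Ct tables, expression
    tables with controlled class fractions) make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
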