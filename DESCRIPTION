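Package: binseqr
Title: Binary Container Formats for Nucleotide Sequence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Readers, writers and processing tools for a family of binary
    nucleotide-sequence container formats: BQ, a fixed-record-size format
    with two-bit or four-bit base packing and O(1) random access to any
    record, and VBQ, a block-structured format for variable-length records
    with optional quality scores, sequence headers and per-block ZSTD
    compression plus a trailing block index for parallel access. Includes a
    FASTQ/FASTA conversion command-line tool, a hook-based map-reduce
    interface for parallel record processing, a deterministic uniform-random
    read generator, and a naive parallel k-mer counter built on the
    processing interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
SystemRequirements: libzstd
Config/testthat/edition: 3
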