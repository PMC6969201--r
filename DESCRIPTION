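Package: fqpack
Title: K-mer-Based Compression of FASTQ Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lossless and optionally lossy compression of short-read FASTQ
    files. Bases are coded by prediction by partial matching over four
    tiered dictionaries of canonical k-mer successor counts, followed by a
    rank transform whose rank frequencies adapt through an aggressive
    dynamic-Markov-coder-like update, and a byte-oriented range coder.
    Sequencing errors are detected and corrected in-stream to keep the
    dictionaries compact; an optional reordering mode sorts reads by
    sequence and delta-codes packed read prefixes; paired-end mates are
    predicted through a dictionary of co-occurring minimizer pairs. Read
    identifiers use tokenized differential coding and quality scores are
    coded at five resolutions under position and history contexts. Includes
    a synthetic short-read generator and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    Rcpp,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
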