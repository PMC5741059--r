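Package: breakendr
Title: Structural Variant Break-End Detection by Positional de Bruijn Graph Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic rearrangements from coordinate-sorted short-read
    alignments by extracting split-read, soft-clip, indel, discordant-pair and
    one-end-anchor evidence, assembling break-end contigs with a positional de
    Bruijn graph, scoring evidence with a Phred-scaled probabilistic model of
    arising without an underlying structural variant, and calling breakpoints
    by maximal-clique enumeration over breakpoint-support rectangles. Calls are
    emitted as VCFv4.2 break-end (BND) records annotated with microhomology,
    inexact homology and untemplated inserted sequence. A synthetic-data module
    generates reference genomes, planted structural variants with known truth,
    and simulated paired-end reads so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    vctrs,
    ggplot2,
    generics,
    withr,
    Rcpp,
    Biostrings,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse,
    readr
Config/testthat/edition: 3
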