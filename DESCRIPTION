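Package: poolscape
Title: Sequence Evolution of Biased Short DNA Pools Under Templated Replication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep-sequenced short single-stranded DNA
    pools evolving under isothermal templated replication. Provides FASTQ
    quality trimming and insert extraction for binary (AT, GC) and quaternary
    pools, positional nucleotide-fraction maps stacked by sequence length,
    periodicity detection via Fourier amplitude spectra of position-conditional
    base probabilities, zebraness and self-complementarity metrics, k-mer
    reverse-complement abundance symmetry, nearest-neighbor stacking
    free-energy comparisons of alternating versus homodimer steps, periodic
    partner-motif combinatorics, and a synthetic-data generator with a toy
    strand-displacement replication simulator that emulates such pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
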