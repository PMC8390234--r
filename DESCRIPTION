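Package: nucstates
Title: Functional Nucleosome States from Histone-Mark Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("nucstates", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns nucleosome-level chromatin states from positioned
    nucleosomes (iNPS-style calls) and histone-mark peak sets using a
    discrete univariate hidden Markov model over a 2^n bitmask alphabet,
    with BIC model selection, low-occupancy state pruning and a second
    training round.  Decoded states are characterized by nucleosome array
    detection, phasing (Welch power spectral density in the 4-10 Hz band of
    the interpolated array signal), spacing (inter-maximum distances) and
    positioning (read-based and nucleosome-call-based scores), annotated to
    gene-centric genomic regions, and scored for skipped-exon splicing
    potentiality via discrete Frechet distance between reliable and
    unreliable event groups.  Includes a synthetic-data generator emitting
    every input format so the full pipeline is testable without external
    sequencing data, plus a subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
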