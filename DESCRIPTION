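Package: DuplexFidelity
Title: Strand-Resolved Polymerase Fidelity from Duplex Consensus Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures RNA polymerase and reverse transcriptase fidelity from
    duplex (first-strand/second-strand) circular-consensus reads of
    reverse-transcribed RNA amplicons. Builds per-strand majority-vote
    consensus sequences from subreads, aligns them to a reference amplicon
    with a banded affine-gap aligner, applies read-level quality filters,
    attributes replication errors to first- or second-strand synthesis by
    duplex confirmation, classifies substitutions into equivalent RNA
    polymerase / reverse transcriptase pairs, and aggregates per-type error
    rates, modified-vs-unmodified fold changes, indel size distributions,
    error hotspots and sequence-context profiles. Includes a truth-annotated
    synthetic-data generator (stage-specific substitution and indel
    injection, repeat slippage, chimeric molecules, per-pass raw noise) so
    the entire pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
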