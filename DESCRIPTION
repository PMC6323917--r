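Package: mirqc
Title: Read-Pattern Confidence Classification and Literature Mining for
    microRNA Annotations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the quality of microRNA hairpin annotations
    from small RNA sequencing read-stack patterns, and to mine scientific
    literature for microRNA functional information. Implements the
    high-confidence classifier based on dual-arm annotation, duplex 3'
    overhang geometry, per-arm read depth and 5' processing homogeneity,
    and the complementary low-confidence flag for deeply covered loci with
    scattered 5' ends. Includes a seeded simulator of Drosha/Dicer
    consistent read stacks, readers and writers for hairpin FASTA,
    dot-bracket structures, mature annotation tables and small RNA
    alignments, and a literature-mining pipeline (microRNA name
    recognition, sentence filtering, species and gene-family assignment,
    functional keyword scoring, article ranking and word-cloud term
    frequencies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
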