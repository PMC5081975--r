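Package: msadiff
Title: Statistical Comparison of Alternative Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the similarities and differences between two
    alternative multiple sequence alignments of the same sequences.
    Columns of a reference alignment are paired with their best-matching
    columns in a comparison alignment via an occurrence-encoded similarity
    matrix, and every reference cell is categorised as a match, conserved
    gap, merge, split, or shift. Provides overall and column-wise summary
    scores, the classical sum-of-pairs and total column scores, four
    standard visualisations, a deterministic synthetic alignment-pair
    generator for testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    seqinr,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
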