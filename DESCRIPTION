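Package: blockorder
Title: Reference-Guided Contig Ordering by Weighted Reversals and
    Block-Interchanges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients the contigs of a draft genome against a
    completely assembled reference genome so that the rearrangement
    distance, measured by reversals (weight 1) and block-interchanges
    (weight 2), between the induced assembly and the reference is
    minimal.  The exact solver works in the permutation-group (cycle
    algebra) representation of double-stranded genomes: contigs are
    capped, cap exchanges and fusions are derived from the cycle
    structure of the quotient permutation, and the optimal event
    sequence of reversals and block-interchanges is then extracted.
    Includes an independent brute-force optimality oracle
    (uniform-cost search over exhaustive contig orderings), a
    simulation benchmark with normalized contig mis-join error, a
    GRIMM-dialect signed gene-order parser, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
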