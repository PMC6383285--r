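Package: apoedit
Title: Detection of Stress-Induced Site-Specific C-to-U RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects hypoxia- and crowding-induced site-specific C>U (and
    A>I) RNA editing from per-site ref/alt read counts in a paired
    normoxia/hypoxia design. Implements per-site paired binomial logistic
    regression with Benjamini-Hochberg FDR control, a three-stage filter
    cascade ending in an APOBEC3-substrate stem-loop structural predicate
    (tri/tetra-loop with the edited C at the loop 3' end), dinucleotide
    context filters and position-frequency-matrix motif summaries,
    contingency/overlap enrichment statistics, Sanger peak-height editing
    quantification, and a synthetic-data generator emulating the paired
    three-donor study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
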