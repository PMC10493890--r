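Package: sortscreen
Title: Sort-Seq Screening of Saturation Mutagenesis Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Design, simulation and analysis of FACS-based sort-seq screens
    of focused saturation mutagenesis libraries. Designs multi-position
    saturation libraries with codon-usage-sampled, GC-constrained DNA;
    simulates the sorting experiment (inducer-dependent fluorescence,
    scatter and fluorescence gating, multi-round positive and negative
    selection, amplicon sequencing); decodes variants from reads and
    computes per-variant and per-position log2 enrichment statistics; and
    derives reporter dose-response performance metrics (EC200, delta-RLU,
    time-to-threshold, cross-strain fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
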