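Package: locsig
Title: Discovery and Validation of mRNA Localization Signals from
    Compartment Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for delimiting minimal mRNA
    localization elements in a 3' UTR. Implements rolling-window
    containment counting and input-normalized compartment enrichment for
    massively parallel localization reporter assays (SLAP-seq style),
    interval logic for deriving a minimal signal from sufficient and
    insufficient reporter windows, per-base boxplot normalization of
    DMS-MaPseq mutation rates into reactivities, and per-cell smFISH
    localization and translation-output scoring with bootstrap fold
    changes. A seeded synthetic-data generator emulates every input so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    graphics,
    grDevices,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
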