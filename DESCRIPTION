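Package: rmconj
Title: Quantifying Restriction-Modification Defence Against Plasmid Conjugation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how bacterial restriction-modification (RM)
    systems limit conjugative plasmid transfer. Scans plasmid sequences for
    IUPAC degenerate (including bipartite) recognition sites with correct
    circular-topology and duplex-strand conventions, computes expected site
    counts under base-composition null models to measure site avoidance,
    converts colony counts from mating assays into transfer efficiencies
    (gamma, ml/cell/h) and restriction-efficiency fold values with
    detection-limit censoring, fits linear models relating restriction
    efficiency to recognition-site numbers, and simulates complete mating
    experiments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    dplyr,
    purrr,
    readr,
    rlang,
    tibble,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
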