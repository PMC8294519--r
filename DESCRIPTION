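Package: sortloc
Title: Sorting-Signal Based Subcellular Localization Prediction for
    Gram-Positive Bacteria
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Meta-prediction of protein subcellular localization in
    Gram-positive bacteria from sorting-signal evidence. Heterogeneous
    evidence (Sec/Tat/lipoprotein signal peptides, transmembrane
    topology, domain signatures, GO compartment terms) is integrated by a
    score/threshold/Boolean-override decision engine with consistency
    resolution of localization tags (cytoplasmic, transmembrane,
    lipoprotein, cell wall, extracellular, Unknown). Includes built-in
    sequence-only detectors (lipobox, twin-arginine, LPXTG,
    Kyte-Doolittle hydropathy, tripartite Sec signal peptides), a curated
    signature catalog, Unknown-aware one-vs-rest evaluation (sensitivity,
    specificity, precision, accuracy, Matthews correlation coefficient)
    with size-weighted overall averages, and a synthetic labeled proteome
    generator for hermetic benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
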