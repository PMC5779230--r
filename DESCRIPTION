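Package: axonreg
Title: Quantification of Maturation-Dependent Axon Regeneration Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how cultured CNS neurons lose axon
    regenerative ability as they mature. Implements feature extraction for
    current-clamp electrophysiology (action-potential detection by a membrane
    potential acceleration criterion, passive membrane properties), kymograph
    vesicle-transport tracking and direction classification under a 2 micron
    displacement rule, laser-axotomy time-course scoring (initial response,
    retraction distance, bulb formation time, regeneration initiation, length
    and growth-cone area), log10-retraction Gaussian mixture modelling with
    BIC model choice, neurite fluorescence polarity ratios with adjacent
    background subtraction, a three-criterion FPKM trend classifier, and the
    test-selection statistics harness the assays require (Student/Welch
    routing, Bartlett-gated post hocs including Games-Howell, Fisher exact
    with Bonferroni, Kruskal-Wallis). Seeded synthetic-data generators plant
    known ground truth for every input type so each stage is verified by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    multcomp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
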