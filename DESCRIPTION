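Package: metaboclass
Title: Metabolome-Based Family Classification of Snake Venoms from LC-MS
    Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying snake venoms into the Elapidae and
    Viperidae families from untargeted LC-MS small-molecule feature tables.
    Per-injection feature lists (m/z, retention time, intensity) are aligned
    across injections into a coherent intensity matrix, cleaned with blank,
    duplicate-presence and prevalence ("Rep") filters, autoscaled and
    decomposed by PCA. Two decision rules operate in score space: a
    nearest-centroid classifier reporting proximity percentages in five
    confidence bins, and a hard-margin linear support vector machine. The
    prevalence threshold is optimized by leave-group-out jackknifing and the
    number of retained principal components is selected against a held-out
    validation subset. A synthetic LC-MS dataset generator with known ground
    truth supports end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
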