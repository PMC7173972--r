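Package: flydyad
Title: Quantification of Optogenetically Evoked Dyadic Social Behavior in Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-to-statistics pipeline for dyadic social-behavior
    assays in Drosophila with optogenetic stimulation. Computes the
    "time orienting" interaction metric from tester/target trajectories,
    post-processes behavior-classifier bout tables (duration filtering,
    per-minute binning), aligns data to an LED stimulation paradigm and
    pools behavior into analysis windows, and applies the exact
    nonparametric testing scheme (Kruskal-Wallis gate, Wilcoxon
    signed-rank, Mann-Whitney U, Fisher's exact test, Bonferroni
    correction) together with responder classification. Also provides
    bout-level classifier evaluation (recall/precision), mirror-averaged
    voxel morphometry with threshold-based volume quantification and
    minimal NRRD I/O, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
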