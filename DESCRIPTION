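Package: microconn
Title: Microstate-Gated Dynamic Functional Connectivity for ERP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing event-related potential (ERP) recordings as a
    sequence of quasi-stable scalp topographies (microstates) that gate
    time-varying functional connectivity. Implements global field power,
    polarity-sensitive topographic K-means clustering with split-half
    cross-validated selection of the number of classes by global explained
    variance, permutation alignment of individual template sets into a global
    mean template, back-fitting and per-class durations, phase-locking value
    (PLV) connectivity from Hilbert-transform phases, weighted and binary
    graph metrics (clustering coefficient, characteristic path length), and a
    mixed-design repeated-measures ANOVA with Mauchly sphericity testing,
    Greenhouse-Geisser correction and Bonferroni post-hoc comparisons. A
    synthetic ERP generator reproduces the experimental design the analysis
    assumes (two groups, three within-subject conditions, microstate-structured
    epochs, controllable phase coupling) so the whole pipeline is testable
    without access to raw EEG.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
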