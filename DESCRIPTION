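Package: bilatrep
Title: Bilateral Tumor TCR Repertoire Comparison and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clone-level comparison of T cell receptor (TCR) beta repertoires
    between paired samples in a bilateral mouse tumor model. Provides readers
    for VDJtools-style and AIRR Rearrangement clone tables, depth
    normalization by without-replacement downsampling to six times the sorted
    cell count, repertoire indices (1 - Pielou clonality, Morisita-Horn
    similarity, geometric-mean overlap frequency, V/J segment usage with
    PCA), Fisher exact differential clone expansion with q-value and
    fold-change thresholds, grouped within/between-mouse comparisons of
    tumors, tumor fragments and draining lymph nodes, and a synthetic data
    generator implementing a proportional-infiltration model (clones primed
    in either draining lymph node mix in circulation and seed both tumors)
    so every analysis stage can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
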