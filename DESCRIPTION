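Package: tadevolve
Title: Evolutionary Conservation of Topologically Associating Domains in
    Syntenic Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the evolutionary conservation of topologically
    associating domains (TADs) within syntenic blocks across a
    time-calibrated phylogeny. Implements TAD-number conservation via the
    average relative difference (ARD) statistic with a block-shuffle
    permutation null, rank-matched TAD border position conservation
    (mean absolute difference and cross-species R-squared), gene-TAD
    positioning with a gene-shuffle null, a partition edit distance
    counting TAD border insertions and deletions, and per-block
    Ornstein-Uhlenbeck model fitting by generalised least squares and
    grid-search maximum likelihood to distinguish stabilising selection
    from genetic drift. Includes a seeded synthetic-data generator that
    emulates syntenic blocks, TAD tracks and trait evolution along a
    phylogeny, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
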