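Package: grnbounds
Title: Ensemble Bounds for Signed Gene Regulatory Network Inference from
    Knock-Out Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ensemble of signed gene regulatory networks consistent
    with steady-state transcriptional profiles of gene knock-out experiments.
    From a complete single-gene knock-out compendium the method builds a signed
    upper bound (z-score accessibility) and lower bound (sign-consistent local
    transitive reduction) of the ensemble; multi-gene knock-out data shrink the
    set of uncertain edges via separatoid-based verification with t-test voting,
    and a greedy experiment-design loop drives the ensemble to a unique network.
    A chemical-Langevin knock-out data simulator makes the whole pipeline
    reproducible in silico, and evaluation metrics (true positive rate, total
    distance, Jaccard distance, error tallies) score inferred bounds against a
    reference network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
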