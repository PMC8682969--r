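Package: netrecov
Title: Disease-Network Construction, NTRA Node Prioritization and
    Drug-Recovery Scoring for Three-Group Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a disease network by restricting a protein-protein
    interaction edge list to disease-associated genes measured in a
    transcriptome study, prioritizes its nodes with the NTRA rank
    aggregation of topology (degree, betweenness) and transcriptome
    (fold change, p-value) ranks, scores per-gene drug response with the
    recovery-level / efficiency-of-recovery (RL/EoR) statistic, selects
    key genes, and tests them for pathway over-representation with a
    hypergeometric test. Includes a negative-binomial generator of
    three-group (Sham/Model/Treated) count studies with planted
    perturbation and recovery structure and a matching scale-free PPI
    graph, so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
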