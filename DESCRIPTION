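Package: moanet
Title: Mechanism-of-Action Inference by Trainable Signal Propagation on
    Protein Interaction Networks
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting drug mechanisms of action on a disease at
    the molecular level. A directed protein-protein interaction network is
    turned into a trainable signal-propagation model: drug targets are
    clamped as inputs, node activities are the sigmoid-normalised sum of
    weighted incoming signals, and edge weights are fitted by simulated
    annealing against a training set of stimulus-to-response rules, yielding
    an ensemble of valid solutions above an accuracy gate. Downstream
    analytics quantify how a treatment reverts disease effector proteins
    (fSignal, reverted-effector classification, per-motive percentages),
    decompose a two-drug combination into convergent and drug-exclusive
    complementary mechanisms, corroborate model behaviour against
    literature-reported bioflags, rank stimulus inputs by variance-based
    Sobol sensitivity, and export mechanism subnetworks as DOT graphs. A
    synthetic-data module generates networks, disease characterizations and
    satisfiable rule sets with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
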