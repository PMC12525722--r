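Package: mvddi
Title: Multi-View Graph Representation Learning for Drug-Drug Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) by coupling two graph
    views of the same pharmacology problem: an inter-view encoder that embeds
    each drug's molecular graph (atoms as nodes, bonds as edges) with a graph
    convolutional network that can be pretrained on unlabeled molecules via
    self-supervised tasks (context prediction, edge prediction, atom-type
    masking), and an intra-view encoder that propagates those embeddings over
    the known DDI network. A link predictor scores drug pairs from the fused
    intra-view embeddings, trained under a composite objective that adds
    output-space matching (a KL penalty tying an auxiliary molecular-view
    predictor to the main predictor) and feature-space matching (a central
    moment discrepancy between the two embedding distributions) to the
    supervised cross-entropy. Includes Bemis-Murcko scaffold-based data
    splitting for out-of-distribution evaluation, a planted-signal synthetic
    data generator, evaluation metrics, ablation switches and hyperparameter
    sweep harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
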