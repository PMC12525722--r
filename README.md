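# mvddi — multi-view graph learning for drug–drug interaction prediction

Predicting drug–drug interactions (DDIs) is a link-prediction problem on
the network of known interactions, and its hard case is pharmacologically
the important one: drugs whose ring frameworks the model has never seen.
`mvddi` is an R implementation of a multi-view graph approach for this
setting, aimed at computational chemists and method developers who want a
self-contained, fully seeded pipeline they can run, ablate and extend on a
laptop.

## The model

Two coupled views of the same question:

* **Inter-view (molecular).** Each drug's molecular graph (heavy atoms as
  nodes with atomic-number/chirality features, bonds as edges with
  type/direction features) is embedded by a 5-layer graph convolutional
  network with batch normalization and mean pooling,
  `H = POOL(Δ̂^{-1/2} Ê Δ̂^{-1/2} V W_p)` layer by layer. The encoder can be
  **pretrained on unlabeled SMILES** by context prediction, edge
  prediction, or atom masking, and fine-tuned afterwards.
* **Intra-view (DDI network).** The molecular embeddings propagate over
  the degree-normalized adjacency `L̂` of the known interaction network:
  `D = ReLU(L̂ ReLU(L̂ H W₀) W₁)`, using train-split links only.
* **Heads.** A pair is fused by the element-wise product `I_ij = d_i ⊙ d_j`
  and scored by a two-layer head, `p_ij = softmax(W_k ReLU(W_I I_ij + b_I)
  + b_k)`; an auxiliary head scores the molecular pair `h_i ⊙ h_j` as
  `q_ij`.
* **Objective.** `L = L_s + α·L_om + γ·L_fm` with defaults `(α, γ) = (1,
  2)`: supervised cross-entropy on both heads, output-space matching
  `Σ KL(p‖q)`, and feature-space matching by the central moment
  discrepancy `‖E(D)−E(H)‖₂ + Σ_{k=2}^{5} ‖C_k(D)−C_k(H)‖₂`.

Evaluation uses **Bemis–Murcko scaffold splitting** (8:1:1, whole scaffold
groups, repeated over seeds), so test links always involve a drug with an
unseen ring framework. A planted-signal synthetic generator (molecule
classes that determine link probability) makes the whole pipeline testable
offline.

## Worked example

Generate a 200-drug synthetic study, pretrain the molecular encoder by
atom masking, scaffold-split, train, and score held-out pairs:

```r
library(mvddi)

spec    <- synthetic_spec(n_drugs = 200, seed = 1)
drugs   <- generate_molecules(spec)
network <- generate_ddi(drugs, spec)
edges   <- data.frame(drug_id_1 = network$drug_ids[network$labeled_pairs$i],
                      drug_id_2 = network$drug_ids[network$labeled_pairs$j])
network
#> <ddi_network> 200 drugs, 6587 positive links, 6587 labeled pairs

pre <- pretrain(generate_pretrain_corpus(200, seed = 1),
                pretrain_config(strategy = "masking_node", epochs = 30,
                                hidden_dim = 32, batch_size = 256, seed = 1))
tail(pre$log, 1)
#>    epoch     loss
#> 30    30 1.785988

cfg  <- experiment_config(hidden_dim = 32, epochs = 60, batch_size = 1024,
                          patience = 10, min_epochs = 20, seeds = 1L)
data <- prepare_ddi_data(drugs, edges, seed = 1, cfg)
data$split
#> <split_assignment> seed 1: train 163 / valid 18 / test 19

model <- train(cfg, data, pretrained = pre$params, seed = 1)
model
#> <ddi_model> 200 drugs, best epoch 6
#>   test: AUROC 0.857 AUPRC 0.779 F1 0.817

test_pairs <- data$pairs[data$pairs$split == "test", ][1:3, ]
predict_ddi(model, data, test_pairs)
#>   drug_id_1 drug_id_2 prob_interaction
#> 1     D0002     D0090        0.3466812
#> 2     D0003     D0021        0.8017200
#> 3     D0003     D0030        0.6730016
```

The masking pretraining loss falls from ~4.7 (near the uniform
`ln 118 ≈ 4.77` over atom types) to 1.79; the trained model ranks held-out
scaffold-split test links at AUROC 0.857 — against a Bayes-optimal ceiling
of ≈ 0.925 for this generator (the link labels themselves are stochastic).
`run_experiment()` repeats split/sample/train/evaluate over several seeds
and aggregates mean ± sd; `sweep_objective()` scans `α` or `γ`;
`experiment_config(ablation = ...)` switches off pretraining
(`no_pretrain`), output matching (`no_om`) or feature matching (`no_fm`).

A thin command-line front end is installed at `exec/mvddi` with
subcommands `simulate`, `pretrain`, `split`, `train`, `evaluate`, `sweep`.

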