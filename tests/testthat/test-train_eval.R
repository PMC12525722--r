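# The end-to-end training loop, its determinism, ablation switches and the
# multi-seed protocol, exercised on a small planted-signal dataset.

small_study <- function(n_drugs = 36, seed = 2) {
  spec <- synthetic_spec(n_drugs = n_drugs, seed = seed)
  drugs <- filter_parseable(generate_molecules(spec))$kept
  net <- generate_ddi(generate_molecules(spec), spec)
  edges <- data.frame(drug_id_1 = net$drug_ids[net$labeled_pairs$i],
                      drug_id_2 = net$drug_ids[net$labeled_pairs$j])
  list(drugs = drugs, edges = edges)
}

test_that("prepare_ddi_data assembles consistent splits and pairs", {
  st <- small_study()
  cfg <- quick_config()
  data <- prepare_ddi_data(st$drugs, st$edges, seed = 1, cfg)
  # link partition is exhaustive and disjoint over labeled pairs
  expect_equal(length(data$link_split), nrow(data$network$labeled_pairs))
  expect_true(all(data$link_split %in% c("train", "valid", "test")))
  # sampled negatives are labeled 0 and carry their split
  negs <- data$pairs[data$pairs$y == 0L, ]
  expect_true(all(negs$split %in% c("train", "valid", "test")))
  # positives and negatives balance per split at ratio 1
  tab <- table(data$pairs$split, data$pairs$y)
  expect_true(all(abs(tab[, "0"] - tab[, "1"]) <= 1))
})

test_that("training is deterministic per seed and learns on planted signal", {
  st <- small_study(n_drugs = 48)
  cfg <- experiment_config(hidden_dim = 16, epochs = 50, batch_size = 256,
                           patience = 50, min_epochs = 50, seeds = 1L)
  data <- prepare_ddi_data(st$drugs, st$edges, seed = 1, cfg)
  m1 <- train(cfg, data, seed = 1)
  m2 <- train(cfg, data, seed = 1)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_log, m2$loss_log)
  # the composite objective must fall substantially on learnable data
  expect_lt(m1$loss_log$total[nrow(m1$loss_log)],
            0.5 * m1$loss_log$total[1])
  expect_s3_class(m1, "ddi_model")
  expect_true(all(c("valid", "test") %in% names(m1$report)))
  expect_error(train(cfg, within(data, pairs <- pairs[0, ])), "train split")
})

test_that("ablation switches map onto the objective weights", {
  st <- small_study()
  base <- experiment_config(hidden_dim = 16, epochs = 4, batch_size = 4096,
                            patience = 10, seeds = 1L)
  data <- prepare_ddi_data(st$drugs, st$edges, seed = 1, base)

  # no_om is exactly alpha = 0
  cfg_ab <- base; cfg_ab$ablation <- "no_om"
  cfg_a0 <- base; cfg_a0$alpha <- 0
  expect_identical(train(cfg_ab, data, seed = 1)$loss_log,
                   train(cfg_a0, data, seed = 1)$loss_log)
  # no_fm is exactly gamma = 0
  cfg_fb <- base; cfg_fb$ablation <- "no_fm"
  cfg_g0 <- base; cfg_g0$gamma <- 0
  expect_identical(train(cfg_fb, data, seed = 1)$loss_log,
                   train(cfg_g0, data, seed = 1)$loss_log)

  # no_pretrain ignores a supplied checkpoint: identical to not passing one
  pre <- init_mol_encoder(16, 5, seed = 77) # stands in for a checkpoint
  cfg_np <- base; cfg_np$ablation <- "no_pretrain"
  expect_identical(train(cfg_np, data, pretrained = pre, seed = 1)$loss_log,
                   train(base, data, seed = 1)$loss_log)
  # ... while a used checkpoint changes the trajectory
  expect_false(identical(train(base, data, pretrained = pre,
                               seed = 1)$loss_log,
                         train(base, data, seed = 1)$loss_log))
})

test_that("deleting test links leaves training bit-identical (no leakage)", {
  st <- small_study(n_drugs = 30, seed = 4)
  cfg <- experiment_config(hidden_dim = 12, epochs = 4, batch_size = 4096,
                           patience = 10, seeds = 1L)
  data_full <- prepare_ddi_data(st$drugs, st$edges, seed = 3, cfg)
  # drop every test link from the *input* edge list and rebuild everything
  lp <- data_full$network$labeled_pairs
  test_rows <- data_full$link_split == "test"
  ids <- data_full$network$drug_ids
  kept_edges <- data.frame(drug_id_1 = ids[lp$i[!test_rows]],
                           drug_id_2 = ids[lp$j[!test_rows]])
  data_trim <- prepare_ddi_data(st$drugs, kept_edges, seed = 3, cfg)
  m_full <- train(cfg, data_full, seed = 3)
  m_trim <- train(cfg, data_trim, seed = 3)
  expect_identical(m_full$weights, m_trim$weights)
})

test_that("run_experiment aggregates per-seed metrics", {
  st <- small_study()
  cfg <- quick_config()
  rep1 <- run_experiment(st$drugs, st$edges, cfg)
  expect_s3_class(rep1, "metric_report")
  expect_equal(unique(rep1$summary$sd), 0) # single seed: no spread
  expect_true(all(rep1$summary$mean >= 0 & rep1$summary$mean <= 1))

  st2 <- small_study(n_drugs = 48, seed = 3)
  cfg3 <- quick_config(); cfg3$seeds <- c(1L, 2L, 3L)
  rep3 <- run_experiment(st2$drugs, st2$edges, cfg3)
  expect_equal(sum(rep3$per_seed$split == "test"), 3L)
  rep3b <- run_experiment(st2$drugs, st2$edges, cfg3)
  expect_identical(rep3$per_seed, rep3b$per_seed) # same seed list twice
})

test_that("sweep_objective varies one weight and keeps the other fixed", {
  st <- small_study()
  cfg <- quick_config()
  sw <- sweep_objective(st$drugs, st$edges, cfg, parameter = "gamma",
                        values = c(0.5, 2))
  expect_equal(sort(unique(sw$gamma)), c(0.5, 2))
  expect_true(all(c("split", "metric", "mean", "sd") %in% names(sw)))
  # a single-value sweep at the base setting reproduces the base run
  sw1 <- sweep_objective(st$drugs, st$edges, cfg, parameter = "alpha",
                         values = 1)
  base <- run_experiment(st$drugs, st$edges, cfg)
  expect_equal(sw1$mean, base$summary$mean)
})

test_that("predict_ddi emits symmetric probabilities for named pairs", {
  st <- small_study()
  cfg <- quick_config()
  data <- prepare_ddi_data(st$drugs, st$edges, seed = 1, cfg)
  model <- train(cfg, data, seed = 1)
  pairs <- data.frame(drug_id_1 = data$drugs$drug_id[c(1, 2)],
                      drug_id_2 = data$drugs$drug_id[c(3, 4)])
  pred <- predict_ddi(model, data, pairs)
  expect_equal(names(pred), c("drug_id_1", "drug_id_2", "prob_interaction"))
  expect_true(all(pred$prob_interaction >= 0 & pred$prob_interaction <= 1))
  flipped <- predict_ddi(model, data,
                         data.frame(drug_id_1 = pairs$drug_id_2,
                                    drug_id_2 = pairs$drug_id_1))
  expect_equal(pred$prob_interaction, flipped$prob_interaction)
})
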