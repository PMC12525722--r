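# End-to-end DDI training: encode every molecule, propagate over the
# train-link DDI network, score drug pairs with both heads, and minimize
# the composite objective with Adam. Includes the repeated-seed experiment
# protocol, ablation switches and hyperparameter sweeps.

#' Experiment configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Maximum training epochs (default 100).
#' @param batch_size Labeled pairs per mini-batch (default 512).
#' @param alpha Weight of output-space matching (default 1).
#' @param gamma Weight of feature-space matching (default 2).
#' @param hidden_dim Embedding width shared by both views (default 300).
#' @param mol_layers Molecular-encoder depth (default 5).
#' @param intra_layers DDI-network-encoder depth (default 2; set 3 for the
#'   deeper variant).
#' @param freeze_pretrained Keep pretrained molecular weights fixed instead
#'   of fine-tuning (default `FALSE`).
#' @param ablation Character subset of `c("no_pretrain", "no_om", "no_fm")`:
#'   random encoder init, drop output-space matching (alpha = 0), drop
#'   feature-space matching (gamma = 0).
#' @param patience Early-stopping patience on validation AUROC (default 10).
#' @param min_epochs Epochs to complete before early stopping may trigger
#'   (default 20): validation AUROC is uninformative during the first
#'   epochs while the deep encoder warms up.
#' @param neg_ratio Negatives sampled per positive link (default 1).
#' @param ratios Train/valid/test drug split fractions (default 8:1:1).
#' @param seeds Integer vector of repetition seeds (default 1:5); each seed
#'   redraws the scaffold shuffle, negative samples and weight init.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(learning_rate = 0.001, epochs = 100L,
                              batch_size = 512L, alpha = 1, gamma = 2,
                              hidden_dim = 300L, mol_layers = 5L,
                              intra_layers = 2L, freeze_pretrained = FALSE,
                              ablation = character(0), patience = 10L,
                              min_epochs = 20L, neg_ratio = 1,
                              ratios = c(0.8, 0.1, 0.1), seeds = 1:5) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L,
            alpha >= 0, gamma >= 0, length(seeds) >= 1L,
            all(ablation %in% c("no_pretrain", "no_om", "no_fm")))
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), alpha = alpha, gamma = gamma,
         hidden_dim = as.integer(hidden_dim),
         mol_layers = as.integer(mol_layers),
         intra_layers = as.integer(intra_layers),
         freeze_pretrained = isTRUE(freeze_pretrained),
         ablation = ablation, patience = as.integer(patience),
         min_epochs = as.integer(min_epochs),
         neg_ratio = neg_ratio, ratios = ratios,
         seeds = as.integer(seeds)),
    class = "experiment_config"
  )
}

#' Split drugs and links and sample negatives for one repetition
#'
#' Parses the drug table, scaffold-splits the drugs, assigns links to
#' splits by endpoint inheritance, and samples per-split negatives — the
#' full data preparation for one seed of the protocol.
#'
#' @param drugs Data frame `drug_id`, `smiles` (a `scaffold` column is
#'   honored, and a `graph` list-column of parsed molecules skips
#'   re-parsing).
#' @param edges Data frame `drug_id_1`, `drug_id_2` (+ optional `label`).
#' @param seed Integer repetition seed.
#' @param config An [experiment_config()].
#' @return List with `drugs` (kept records incl. graphs and scaffolds),
#'   `network`, `split` (the [scaffold_split()]), `link_split`, `pairs`
#'   (data frame `i`, `j`, `y`, `split` of positives plus sampled
#'   negatives).
#' @export
prepare_ddi_data <- function(drugs, edges, seed, config = experiment_config()) {
  if (!("graph" %in% names(drugs))) {
    fp <- filter_parseable(drugs)
    drugs <- fp$kept
  }
  if (!("scaffold" %in% names(drugs))) {
    drugs$scaffold <- vapply(drugs$graph, function(g) {
      bemis_murcko_scaffold(g)
    }, character(1))
  }
  keep_edges <- edges$drug_id_1 %in% drugs$drug_id &
    edges$drug_id_2 %in% drugs$drug_id
  network <- ddi_network(drugs$drug_id, edges[keep_edges, , drop = FALSE])
  split <- scaffold_split(drugs, ratios = config$ratios, seed = seed)
  link_split <- split_links(network, split$drug_split)
  negatives <- sample_negative_links(network, split$drug_split, link_split,
                                     ratio = config$neg_ratio, seed = seed)
  lp <- network$labeled_pairs
  pos <- data.frame(i = lp$i, j = lp$j, y = lp$y, split = link_split)
  pairs <- rbind(pos, negatives)
  rownames(pairs) <- NULL
  list(drugs = drugs, network = network, split = split,
       link_split = link_split, pairs = pairs)
}

.flatten_weights <- function(mol, net, pred) {
  c(stats::setNames(unclass(mol), paste0("mol.", names(mol))),
    stats::setNames(unclass(net), paste0("net.", names(net))),
    stats::setNames(unclass(pred), paste0("pred.", names(pred))))
}

.unflatten_weights <- function(flat, config) {
  pick <- function(prefix) {
    sel <- flat[startsWith(names(flat), prefix)]
    stats::setNames(sel, substring(names(sel), nchar(prefix) + 1L))
  }
  list(
    mol = structure(pick("mol."), hidden_dim = config$hidden_dim,
                    num_layers = config$mol_layers,
                    class = c("mol_encoder_params", "list")),
    net = structure(pick("net."), hidden_dim = config$hidden_dim,
                    num_layers = config$intra_layers,
                    class = c("net_encoder_params", "list")),
    pred = structure(pick("pred."), dg = config$hidden_dim,
                     hidden = config$hidden_dim,
                     class = c("predictor_params", "list"))
  )
}

# forward pass from parameter nodes to the two heads' logits for a set of
# pairs; also returns the embedding nodes for the feature-matching term
.ddi_forward <- function(pnodes, batch, Snode, pairs_i, pairs_j, config) {
  mol_nodes <- pnodes[startsWith(names(pnodes), "mol.")]
  names(mol_nodes) <- substring(names(mol_nodes), 5L)
  net_nodes <- pnodes[startsWith(names(pnodes), "net.")]
  names(net_nodes) <- substring(names(net_nodes), 5L)
  pred_nodes <- pnodes[startsWith(names(pnodes), "pred.")]
  names(pred_nodes) <- substring(names(pred_nodes), 6L)
  H <- .mol_forward(mol_nodes, batch, config$mol_layers, pool = TRUE)$pooled
  D <- .net_forward(net_nodes, Snode, H, config$intra_layers)
  I <- ad_mul(ad_gather(D, pairs_i), ad_gather(D, pairs_j))
  logits_p <- .predict_main_logits(pred_nodes, I)
  Hpair <- ad_mul(ad_gather(H, pairs_i), ad_gather(H, pairs_j))
  logits_q <- .predict_aux_logits(pred_nodes, Hpair)
  list(H = H, D = D, logits_p = logits_p, logits_q = logits_q)
}

.softmax_rows_plain <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# interaction scores (probability of the positive class) for pairs, given
# plain weight matrices
.score_pairs <- function(flat, batch, S, pairs, config) {
  tape <- ad_tape()
  pnodes <- ad_consts_in(tape, flat)
  fw <- .ddi_forward(pnodes, batch, ad_const(tape, S), pairs$i, pairs$j,
                     config)
  p <- .softmax_rows_plain(fw$logits_p$value)
  q <- .softmax_rows_plain(fw$logits_q$value)
  list(p = p, q = q, scores = p[, 2L])
}

.split_metrics <- function(scores, labels) {
  fa <- f1_accuracy(scores, labels)
  c(auroc = auroc(scores, labels), auprc = auprc(scores, labels), fa)
}

#' Train the multi-view DDI model
#'
#' Per epoch: all molecules are encoded, the embeddings are propagated over
#' the train-link DDI adjacency, mini-batches of labeled pairs are scored
#' by both heads, and the composite objective (supervised cross-entropy +
#' alpha x output matching + gamma x feature matching) is minimized with
#' Adam. Model selection keeps the epoch with the best validation AUROC;
#' training stops early when it has not improved for `config$patience`
#' epochs. Fully deterministic for a given seed.
#'
#' @param config An [experiment_config()].
#' @param data A prepared repetition from [prepare_ddi_data()].
#' @param pretrained Optional pretrained `mol_encoder_params` (ignored under
#'   the `no_pretrain` ablation).
#' @param seed Integer seed for weight init and batch order.
#' @return Object of class `ddi_model`: `weights` (mol/net/pred), `report`
#'   (validation and test metrics at the selected epoch), `loss_log` (per
#'   epoch components), `best_epoch`, `config`, plus the train adjacency
#'   needed to reproduce scores.
#' @export
train <- function(config, data, pretrained = NULL, seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  pairs <- data$pairs
  train_pairs <- pairs[pairs$split == "train", , drop = FALSE]
  valid_pairs <- pairs[pairs$split == "valid", , drop = FALSE]
  test_pairs <- pairs[pairs$split == "test", , drop = FALSE]
  if (!nrow(train_pairs) || !any(train_pairs$y == 1L)) {
    stop("empty train split")
  }
  alpha <- if ("no_om" %in% config$ablation) 0 else config$alpha
  gamma <- if ("no_fm" %in% config$ablation) 0 else config$gamma
  use_pre <- !is.null(pretrained) && !("no_pretrain" %in% config$ablation)
  mol <- if (use_pre) pretrained else
    init_mol_encoder(config$hidden_dim, config$mol_layers, seed = seed)
  stopifnot(attr(mol, "hidden_dim") == config$hidden_dim,
            attr(mol, "num_layers") == config$mol_layers)
  net <- init_net_encoder(config$hidden_dim, config$intra_layers,
                          seed = seed)
  pred <- init_predictor(config$hidden_dim, seed = seed)
  flat <- .flatten_weights(mol, net, pred)
  trainable <- if (config$freeze_pretrained) {
    names(flat)[!startsWith(names(flat), "mol.")]
  } else names(flat)
  batch <- build_mol_batch(data$drugs$graph)
  train_links <- train_pairs[train_pairs$y == 1L, c("i", "j")]
  S <- normalize_adjacency(adjacency_matrix(data$network, train_links))
  opt <- adam_state(flat[trainable], lr = config$learning_rate)
  n_tr <- nrow(train_pairs)
  loss_log <- data.frame(epoch = integer(0), Ls = numeric(0),
                         Lom = numeric(0), Lfm = numeric(0),
                         total = numeric(0), val_auroc = numeric(0))
  best <- list(auroc = -Inf, flat = flat, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(.sub_seed(seed, epoch, salt = 2L),
                            sample.int(n_tr))
    starts <- seq(1L, n_tr, by = config$batch_size)
    comp <- matrix(0, length(starts), 4L)
    for (bi in seq_along(starts)) {
      sel <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n_tr)]
      pb <- train_pairs[sel, , drop = FALSE]
      m <- nrow(pb)
      tape <- ad_tape()
      pnodes <- c(ad_params_in(tape, flat[trainable]),
                  ad_consts_in(tape, flat[setdiff(names(flat), trainable)]))
      pnodes <- pnodes[names(flat)]
      fw <- .ddi_forward(pnodes, batch, ad_const(tape, S), pb$i, pb$j,
                         config)
      # the objective sums over links (no per-batch averaging): the
      # supervised term must outweigh the population-level matching terms
      Ls <- ad_add(ad_ce_logits(fw$logits_p, pb$y + 1L),
                   ad_ce_logits(fw$logits_q, pb$y + 1L))
      Lom <- .ad_kl_from_logits(fw$logits_p, fw$logits_q)
      touched <- sort(unique(c(pb$i, pb$j)))
      Lfm <- .ad_cmd(ad_gather(fw$D, touched), ad_gather(fw$H, touched),
                     K = 5L)
      total <- ad_add(Ls, ad_add(ad_scale(Lom, alpha),
                                 ad_scale(Lfm, gamma)))
      ad_backward(tape, total)
      step <- adam_step(opt, flat[trainable],
                        ad_grads_out(pnodes[trainable]))
      opt <- step$state
      flat[trainable] <- step$params
      # logged per link for readability; optimization uses the sums
      comp[bi, ] <- c(Ls$value / m, Lom$value / m, Lfm$value,
                      total$value / m)
    }
    val_auroc <- if (nrow(valid_pairs) &&
                     length(unique(valid_pairs$y)) == 2L) {
      sc <- .score_pairs(flat, batch, S, valid_pairs, config)
      auroc(sc$scores, valid_pairs$y)
    } else NA_real_
    loss_log <- rbind(loss_log, data.frame(
      epoch = epoch, Ls = mean(comp[, 1L]), Lom = mean(comp[, 2L]),
      Lfm = mean(comp[, 3L]), total = mean(comp[, 4L]),
      val_auroc = val_auroc))
    track <- if (is.na(val_auroc)) -mean(comp[, 4L]) else val_auroc
    if (track > best$auroc + 1e-12) {
      best <- list(auroc = track, flat = flat, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience && epoch >= config$min_epochs) break
    }
  }
  flat <- best$flat
  report <- list()
  for (sp in c("valid", "test")) {
    ps <- pairs[pairs$split == sp, , drop = FALSE]
    if (nrow(ps) && length(unique(ps$y)) == 2L) {
      sc <- .score_pairs(flat, batch, S, ps, config)
      report[[sp]] <- .split_metrics(sc$scores, ps$y)
    }
  }
  structure(
    list(weights = .unflatten_weights(flat, config), report = report,
         loss_log = loss_log, best_epoch = best$epoch, config = config,
         train_links = train_links, drug_ids = data$drugs$drug_id),
    class = "ddi_model"
  )
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf("<ddi_model> %d drugs, best epoch %d\n",
              length(x$drug_ids), x$best_epoch))
  if (!is.null(x$report$test)) {
    cat(sprintf("  test: AUROC %.3f AUPRC %.3f F1 %.3f\n",
                x$report$test[["auroc"]], x$report$test[["auprc"]],
                x$report$test[["f1"]]))
  }
  invisible(x)
}

#' Score drug pairs with a trained model
#'
#' @param model A `ddi_model` from [train()].
#' @param data The prepared data the model was trained on (drug order must
#'   match).
#' @param pairs Data frame with columns `i`, `j` (indices into the drug
#'   table) or `drug_id_1`, `drug_id_2`.
#' @return Data frame `drug_id_1`, `drug_id_2`, `prob_interaction`.
#' @export
predict_ddi <- function(model, data, pairs) {
  stopifnot(inherits(model, "ddi_model"))
  if (!all(c("i", "j") %in% names(pairs))) {
    pairs <- data.frame(i = match(pairs$drug_id_1, data$drugs$drug_id),
                        j = match(pairs$drug_id_2, data$drugs$drug_id))
    if (anyNA(pairs$i) || anyNA(pairs$j)) stop("unknown drug id in pairs")
  }
  flat <- .flatten_weights(model$weights$mol, model$weights$net,
                           model$weights$pred)
  batch <- build_mol_batch(data$drugs$graph)
  S <- normalize_adjacency(adjacency_matrix(data$network,
                                            model$train_links))
  sc <- .score_pairs(flat, batch, S, pairs, model$config)
  data.frame(drug_id_1 = data$drugs$drug_id[pairs$i],
             drug_id_2 = data$drugs$drug_id[pairs$j],
             prob_interaction = sc$scores)
}

#' Run the repeated-seed experiment protocol
#'
#' For each seed: re-split the drugs by scaffold, resample negatives,
#' retrain, and evaluate on the held-out test links; then aggregate the
#' metrics as mean and standard deviation across seeds.
#'
#' @param drugs,edges Input tables as in [prepare_ddi_data()].
#' @param config An [experiment_config()] (its `seeds` drive the loop).
#' @param pretrained Optional pretrained `mol_encoder_params`.
#' @return Object of class `metric_report`: `per_seed` (one row per seed
#'   and split) and `summary` (mean and sd per metric and split).
#' @export
run_experiment <- function(drugs, edges, config = experiment_config(),
                           pretrained = NULL) {
  if (!("graph" %in% names(drugs))) drugs <- filter_parseable(drugs)$kept
  if (!("scaffold" %in% names(drugs))) {
    drugs$scaffold <- vapply(drugs$graph, bemis_murcko_scaffold, character(1))
  }
  rows <- list()
  for (seed in config$seeds) {
    data <- prepare_ddi_data(drugs, edges, seed, config)
    model <- train(config, data, pretrained = pretrained, seed = seed)
    for (sp in names(model$report)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, split = sp, t(model$report[[sp]]))
    }
  }
  per_seed <- do.call(rbind, rows)
  metrics <- c("auroc", "auprc", "f1", "accuracy")
  summ <- do.call(rbind, lapply(split(per_seed, per_seed$split), function(d) {
    data.frame(split = d$split[1L], metric = metrics,
               mean = vapply(metrics, function(m) mean(d[[m]]), numeric(1)),
               sd = vapply(metrics, function(m) stats::sd(d[[m]]), numeric(1)))
  }))
  summ$sd[is.na(summ$sd)] <- 0
  rownames(summ) <- NULL
  structure(list(per_seed = per_seed, summary = summ, config = config),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sweep one objective weight
#'
#' Re-runs the full repeated-seed protocol for each value of `alpha` or
#' `gamma` while the other weight stays fixed.
#'
#' @param drugs,edges Input tables.
#' @param config Base [experiment_config()].
#' @param parameter `"alpha"` or `"gamma"`.
#' @param values Numeric values to sweep.
#' @param pretrained Optional pretrained encoder.
#' @return Data frame: one row per value, split and metric.
#' @export
sweep_objective <- function(drugs, edges, config = experiment_config(),
                            parameter = c("alpha", "gamma"),
                            values = c(0.5, 1.0, 1.5, 2, 2.5),
                            pretrained = NULL) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1L)
  if (!("graph" %in% names(drugs))) drugs <- filter_parseable(drugs)$kept
  if (!("scaffold" %in% names(drugs))) {
    drugs$scaffold <- vapply(drugs$graph, bemis_murcko_scaffold, character(1))
  }
  out <- list()
  for (v in values) {
    cfg <- config
    cfg[[parameter]] <- v
    rep <- run_experiment(drugs, edges, cfg, pretrained = pretrained)
    s <- rep$summary
    s[[parameter]] <- v
    out[[length(out) + 1L]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
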