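# Self-supervised pretraining of the molecular encoder.
#
# Three strategies, all operating on unlabeled molecules:
#   context_pred — predict whether a center atom's substructure embedding
#     matches its own surrounding context subgraph (vs. contexts of other
#     molecules in the batch), with a separate auxiliary encoder for the
#     context;
#   edge_pred   — hide a fraction of bonds from message passing and predict
#     their presence from the incident atom states;
#   masking_node — replace atom types with a mask token and recover the
#     original atomic number from the final atom states with a linear head.

#' Pretraining configuration
#'
#' @param strategy One of `"context_pred"`, `"edge_pred"`, `"masking_node"`.
#' @param epochs Training epochs (default 100).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Molecules per batch (default 256).
#' @param hidden_dim Encoder width (default 300).
#' @param num_layers Encoder depth (default 5).
#' @param mask_rate Fraction of atoms masked / bonds hidden (default 0.15).
#' @param r1,r2 Inner and outer hop radii of the context region (defaults 4
#'   and 7; small molecules warrant smaller radii).
#' @param neg_per_pos Negative contexts per positive (default 1).
#' @param aux_layers Depth of the context (auxiliary) encoder (default 3).
#' @param seed Master seed: controls initialization, batch order, masking,
#'   edge hiding and negative draws.
#' @return Object of class `pretrain_config`.
#' @export
pretrain_config <- function(strategy = c("masking_node", "edge_pred",
                                         "context_pred"),
                            epochs = 100L, learning_rate = 0.001,
                            batch_size = 256L, hidden_dim = 300L,
                            num_layers = 5L, mask_rate = 0.15,
                            r1 = 4L, r2 = 7L, neg_per_pos = 1L,
                            aux_layers = 3L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(epochs >= 0L, learning_rate > 0, batch_size >= 1L,
            hidden_dim >= 1L, num_layers >= 1L,
            mask_rate > 0, mask_rate < 1, r1 >= 1L, r2 > r1,
            neg_per_pos >= 1L)
  structure(
    list(strategy = strategy, epochs = as.integer(epochs),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         hidden_dim = as.integer(hidden_dim),
         num_layers = as.integer(num_layers), mask_rate = mask_rate,
         r1 = as.integer(r1), r2 = as.integer(r2),
         neg_per_pos = as.integer(neg_per_pos),
         aux_layers = as.integer(aux_layers), seed = as.integer(seed)),
    class = "pretrain_config"
  )
}

# derived sub-seed for a (master seed, epoch, batch) draw, kept in 32-bit
# integer range
.sub_seed <- function(seed, epoch, batch = 0L, salt = 0L) {
  as.integer((as.double(seed) * 100003 + epoch * 1009 + batch * 131 +
                salt * 17) %% 2147480000)
}

#' Substructure / context decomposition around a center atom
#'
#' The substructure is the induced subgraph of atoms within `r1` hops of the
#' center; the context is the induced subgraph of atoms at hop distance in
#' `[r1, r2]` (the ring at exactly `r1` is shared, so the two regions
#' overlap there); the anchors are the shared atoms at distance exactly
#' `r1`. Molecules too small to have any atom beyond `r1` hops yield an
#' empty context, flagged so callers can skip them.
#'
#' @param g A `mol_graph`.
#' @param center Atom index (1-based).
#' @param r1,r2 Hop radii, `r1 < r2`.
#' @return List with `substructure` (a `mol_graph`), `context` (a
#'   `mol_graph` or `NULL`), `anchors` (atom indices of `g`),
#'   `center_in_sub` (index of the center inside the substructure) and
#'   `empty_context` flag.
#' @export
extract_context <- function(g, center, r1, r2) {
  stopifnot(is_mol_graph(g), r1 < r2)
  center <- as.integer(center)
  if (center < 1L || center > g$n_atoms) stop("invalid center atom")
  dist <- .mol_hops(g, center)
  sub_atoms <- which(dist <= r1)
  ctx_atoms <- which(dist >= r1 & dist <= r2)
  anchors <- which(dist == r1)
  beyond <- any(dist > r1 & dist <= r2)
  empty <- !beyond # nothing outside the substructure to predict
  list(
    substructure = .mol_induce(g, sub_atoms),
    context = if (empty) NULL else .mol_induce(g, ctx_atoms),
    anchors = anchors,
    center_in_sub = match(center, sub_atoms),
    empty_context = empty
  )
}

# ---- strategy forward passes (tape) -------------------------------------
# each returns list(loss = scalar node, n = number of scored examples) or
# NULL when the batch yields nothing scoreable

.context_pred_forward <- function(tape, pmain, paux, graphs, config, seed) {
  picks <- withr::with_seed(seed, lapply(graphs, function(g) {
    center <- sample.int(g$n_atoms, 1L)
    extract_context(g, center, config$r1, config$r2)
  }))
  usable <- which(vapply(picks, function(p) {
    !p$empty_context && length(p$anchors) > 0L
  }, logical(1)))
  if (!length(usable)) return(NULL)
  subs <- lapply(picks[usable], `[[`, "substructure")
  ctxs <- lapply(picks[usable], `[[`, "context")
  sub_batch <- build_mol_batch(subs)
  ctx_batch <- build_mol_batch(ctxs)
  sub_fw <- .mol_forward(pmain, sub_batch, config$num_layers, pool = FALSE)
  ctx_fw <- .mol_forward(paux, ctx_batch, config$aux_layers, pool = FALSE)
  # center atom state from the substructure view
  offs_sub <- cumsum(c(0L, sub_batch$sizes[-length(subs)]))
  center_rows <- offs_sub + vapply(picks[usable], `[[`, integer(1),
                                   "center_in_sub")
  centers <- ad_gather(sub_fw$nodes, center_rows)
  # context representation = mean over anchor atoms in the context view
  offs_ctx <- cumsum(c(0L, ctx_batch$sizes[-length(ctxs)]))
  anchor_rows <- integer(0)
  anchor_grp <- integer(0)
  for (k in seq_along(usable)) {
    pk <- picks[[usable[k]]]
    rows <- offs_ctx[k] + match(pk$anchors, pk$context$parent_atoms)
    anchor_rows <- c(anchor_rows, rows)
    anchor_grp <- c(anchor_grp, rep.int(k, length(rows)))
  }
  counts <- tabulate(anchor_grp, nbins = length(usable))
  ctx_rep <- ad_scale_rows(
    ad_rowsum_by(ad_gather(ctx_fw$nodes, anchor_rows), anchor_grp,
                 length(usable)),
    1 / counts
  )
  scores <- list(ad_rows_dot(centers, ctx_rep))
  labels <- list(rep.int(1L, length(usable)))
  if (length(usable) >= 2L) {
    for (s in seq_len(config$neg_per_pos)) {
      shift <- ((seq_along(usable) + s - 1L) %% length(usable)) + 1L
      scores[[length(scores) + 1L]] <-
        ad_rows_dot(centers, ad_gather(ctx_rep, shift))
      labels[[length(labels) + 1L]] <- rep.int(0L, length(usable))
    }
  }
  losses <- mapply(function(sc, lb) ad_bce_logits(sc, lb), scores, labels,
                   SIMPLIFY = FALSE)
  total <- ad_addn(losses)
  n <- sum(vapply(labels, length, integer(1)))
  list(loss = ad_scale(total, 1 / n), n = n)
}

.edge_pred_forward <- function(tape, pmain, graphs, config, seed) {
  graphs <- Filter(function(g) nrow(g$bonds) >= 1L, graphs)
  if (!length(graphs)) stop("edge prediction needs molecules with bonds")
  plan <- withr::with_seed(seed, lapply(graphs, function(g) {
    nb <- nrow(g$bonds)
    nh <- max(1L, round(config$mask_rate * nb))
    hidden <- sort(sample.int(nb, nh))
    # non-bonded negative pairs within the same molecule
    bonded <- paste(g$bonds$i, g$bonds$j)
    all_pairs <- if (g$n_atoms >= 2L) utils::combn(g$n_atoms, 2L) else
      matrix(integer(0), 2L)
    free <- which(!(paste(all_pairs[1L, ], all_pairs[2L, ]) %in% bonded))
    negs <- if (length(free)) {
      free[sample.int(length(free), min(nh, length(free)))]
    } else integer(0)
    list(hidden = hidden,
         neg = all_pairs[, negs, drop = FALSE])
  }))
  visible <- mapply(function(g, pl) {
    g2 <- g
    g2$bonds <- g$bonds[-pl$hidden, , drop = FALSE]
    g2
  }, graphs, plan, SIMPLIFY = FALSE)
  batch <- build_mol_batch(visible)
  fw <- .mol_forward(pmain, batch, config$num_layers, pool = FALSE)
  offs <- cumsum(c(0L, batch$sizes[-length(graphs)]))
  pos_u <- pos_v <- neg_u <- neg_v <- integer(0)
  for (k in seq_along(graphs)) {
    hb <- graphs[[k]]$bonds[plan[[k]]$hidden, , drop = FALSE]
    pos_u <- c(pos_u, offs[k] + hb$i)
    pos_v <- c(pos_v, offs[k] + hb$j)
    ng <- plan[[k]]$neg
    if (length(ng)) {
      neg_u <- c(neg_u, offs[k] + ng[1L, ])
      neg_v <- c(neg_v, offs[k] + ng[2L, ])
    }
  }
  u <- c(pos_u, neg_u)
  v <- c(pos_v, neg_v)
  y <- c(rep.int(1L, length(pos_u)), rep.int(0L, length(neg_u)))
  scores <- ad_rows_dot(ad_gather(fw$nodes, u), ad_gather(fw$nodes, v))
  list(loss = ad_scale(ad_bce_logits(scores, y), 1 / length(y)),
       n = length(y))
}

.masking_node_forward <- function(tape, pmain, phead, graphs, config, seed) {
  batch <- build_mol_batch(graphs)
  offs <- cumsum(c(0L, batch$sizes[-length(graphs)]))
  masked <- withr::with_seed(seed, {
    unlist(lapply(seq_along(graphs), function(k) {
      na <- graphs[[k]]$n_atoms
      nm <- max(1L, round(config$mask_rate * na))
      offs[k] + sample.int(na, nm)
    }), use.names = FALSE)
  })
  at <- batch$atom_type
  truth <- at[masked]
  at[masked] <- .ATOM_MASK_TOKEN
  fw <- .mol_forward(pmain, batch, config$num_layers, pool = FALSE,
                     atom_type = at)
  logits <- ad_add(ad_mm(ad_gather(fw$nodes, masked), phead$head_W),
                   phead$head_b)
  list(loss = ad_scale(ad_ce_logits(logits, truth), 1 / length(masked)),
       n = length(masked), logits = logits, truth = truth)
}

# ---- public loss surfaces (no backward) ---------------------------------

#' Context-prediction pretraining loss of a batch
#'
#' Positive scores pair each usable center atom's substructure state with
#' its own context representation; negatives pair it with contexts of other
#' molecules in the batch. Mean binary cross-entropy on the sigmoid scores.
#'
#' @param main_params,aux_params Encoder parameters ([init_mol_encoder()]);
#'   the auxiliary encoder embeds the context region.
#' @param molecules List of `mol_graph` objects.
#' @param config A [pretrain_config()].
#' @return Scalar mean loss.
#' @export
context_pred_loss <- function(main_params, aux_params, molecules, config) {
  tape <- ad_tape()
  fw <- .context_pred_forward(tape, ad_consts_in(tape, main_params),
                              ad_consts_in(tape, aux_params),
                              molecules, config,
                              .sub_seed(config$seed, 0L))
  if (is.null(fw)) stop("no molecule in the batch has a non-empty context")
  as.numeric(fw$loss$value)
}

#' Edge-prediction pretraining loss of a batch
#'
#' A seeded random subset of bonds is hidden from message passing; hidden
#' bonds are scored positive, an equal number of sampled non-bonded atom
#' pairs negative, scores being dot products of the atom states. Mean binary
#' cross-entropy.
#'
#' @inheritParams context_pred_loss
#' @param params Encoder parameters.
#' @return Scalar mean loss.
#' @export
edge_pred_loss <- function(params, molecules, config) {
  tape <- ad_tape()
  fw <- .edge_pred_forward(tape, ad_consts_in(tape, params), molecules,
                           config, .sub_seed(config$seed, 0L))
  as.numeric(fw$loss$value)
}

#' Atom-masking pretraining loss of a batch
#'
#' `round(mask_rate * n_atoms)` atoms per molecule (at least one) are
#' replaced by the mask token; a linear head on the final atom states
#' predicts the original atomic-number index. Mean cross-entropy over masked
#' positions.
#'
#' @inheritParams edge_pred_loss
#' @param head Named list with `head_W` (`hidden_dim x 118` matrix) and
#'   `head_b`; created by [pretrain()] or [init_masking_head()].
#' @return Scalar mean loss.
#' @export
masking_node_loss <- function(params, head, molecules, config) {
  tape <- ad_tape()
  fw <- .masking_node_forward(tape, ad_consts_in(tape, params),
                              ad_consts_in(tape, head), molecules, config,
                              .sub_seed(config$seed, 0L))
  as.numeric(fw$loss$value)
}

#' Initialize the atom-type prediction head for masking pretraining
#'
#' @param hidden_dim Encoder width.
#' @param seed Integer seed.
#' @return Named list with `head_W`, `head_b` (one logit per atomic-number
#'   index, mask token excluded).
#' @export
init_masking_head <- function(hidden_dim, seed = 1L) {
  withr::with_seed(seed + 3L, list(
    head_W = .xavier(hidden_dim, .NUM_ATOM_TYPES - 1L),
    head_b = matrix(0, 1L, .NUM_ATOM_TYPES - 1L)
  ))
}

#' Pretrain the molecular encoder on an unlabeled corpus
#'
#' Runs the selected self-supervised strategy with Adam for
#' `config$epochs`, fully seeded: the same corpus, configuration and seed
#' give bit-identical weights. With `epochs = 0` the freshly initialized
#' weights are returned unchanged.
#'
#' @param corpus List of `mol_graph` objects (or character SMILES, parsed on
#'   the fly; unparseable entries are an error).
#' @param config A [pretrain_config()].
#' @return Object of class `pretrain_result`: `params` (the encoder,
#'   `mol_encoder_params`), `aux` (strategy-specific auxiliary weights:
#'   context encoder or masking head), `log` (data frame of per-epoch mean
#'   loss) and `config`.
#' @export
pretrain <- function(corpus, config = pretrain_config()) {
  stopifnot(inherits(config, "pretrain_config"), length(corpus) >= 1L)
  if (is.character(corpus)) {
    corpus <- lapply(corpus, parse_smiles)
    if (!all(vapply(corpus, is_mol_graph, logical(1)))) {
      stop("corpus contains unparseable SMILES")
    }
  }
  params <- init_mol_encoder(config$hidden_dim, config$num_layers,
                             seed = config$seed)
  aux <- switch(
    config$strategy,
    context_pred = unclass(init_mol_encoder(config$hidden_dim,
                                            config$aux_layers,
                                            seed = config$seed + 11L)),
    masking_node = init_masking_head(config$hidden_dim, config$seed),
    edge_pred = list()
  )
  if (config$epochs == 0L) {
    return(structure(list(params = params, aux = aux,
                          log = data.frame(epoch = integer(0),
                                           loss = numeric(0)),
                          config = config),
                     class = "pretrain_result"))
  }
  # prefixed names keep main-encoder and auxiliary weights distinct in the
  # flat parameter list (the context encoder shares its field names)
  flat <- c(stats::setNames(unclass(params),
                            paste0("enc.", names(params))),
            if (length(aux)) {
              stats::setNames(aux, paste0("aux.", names(aux)))
            })
  n_enc <- length(unclass(params))
  strip <- function(nodes, prefix) {
    stats::setNames(nodes, substring(names(nodes), nchar(prefix) + 1L))
  }
  opt <- adam_state(flat, lr = config$learning_rate)
  log <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)
  n_mol <- length(corpus)
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(.sub_seed(config$seed, epoch, salt = 1L),
                            sample.int(n_mol))
    starts <- seq(1L, n_mol, by = config$batch_size)
    epoch_losses <- c()
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n_mol)]
      graphs <- corpus[idx]
      seed_b <- .sub_seed(config$seed, epoch, bi)
      tape <- ad_tape()
      pnodes <- ad_params_in(tape, flat)
      penc <- strip(pnodes[seq_len(n_enc)], "enc.")
      paux <- strip(pnodes[-seq_len(n_enc)], "aux.")
      fw <- switch(
        config$strategy,
        context_pred = .context_pred_forward(tape, penc, paux, graphs,
                                             config, seed_b),
        edge_pred = .edge_pred_forward(tape, penc, graphs, config, seed_b),
        masking_node = .masking_node_forward(tape, penc, paux, graphs,
                                             config, seed_b)
      )
      if (is.null(fw)) next
      ad_backward(tape, fw$loss)
      step <- adam_step(opt, flat, ad_grads_out(pnodes))
      opt <- step$state
      flat <- step$params
      epoch_losses <- c(epoch_losses, as.numeric(fw$loss$value))
    }
    log$loss[epoch] <- mean(epoch_losses)
  }
  out_params <- structure(strip(flat[seq_len(n_enc)], "enc."),
                          hidden_dim = config$hidden_dim,
                          num_layers = config$num_layers,
                          class = c("mol_encoder_params", "list"))
  out_aux <- strip(flat[-seq_len(n_enc)], "aux.")
  if (config$strategy == "context_pred") {
    out_aux <- structure(out_aux, hidden_dim = config$hidden_dim,
                         num_layers = config$aux_layers,
                         class = c("mol_encoder_params", "list"))
  }
  structure(list(params = out_params, aux = out_aux, log = log,
                 config = config),
            class = "pretrain_result")
}

#' Masked-atom prediction accuracy on held-out molecules
#'
#' Applies the masking protocol to fresh molecules and reports the fraction
#' of masked atoms whose atomic number the trained head recovers — the
#' sanity metric for masking pretraining (to beat: the corpus majority-class
#' rate).
#'
#' @param result A `pretrain_result` from masking-node [pretrain()].
#' @param molecules Held-out `mol_graph` list.
#' @param seed Seed for the mask draw.
#' @return Scalar accuracy in \[0, 1\].
#' @export
masking_node_accuracy <- function(result, molecules, seed = 99L) {
  stopifnot(inherits(result, "pretrain_result"),
            result$config$strategy == "masking_node")
  tape <- ad_tape()
  fw <- .masking_node_forward(tape, ad_consts_in(tape, result$params),
                              ad_consts_in(tape, result$aux), molecules,
                              result$config, seed)
  pred <- max.col(fw$logits$value)
  mean(pred == fw$truth)
}
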