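# Shared fixtures: tiny molecules, toy networks and independent dense
# oracles used across the test files. Everything is built in code.

# a small stable of parseable molecules spanning rings, heteroatoms and
# acyclic chains
fixture_smiles <- function() {
  c("C", "CCO", "c1ccccc1", "CCc1ccccc1", "C1CCNCC1", "c1ccncc1",
    "CC(C)Cc1ccc(C)cc1", "C1CCOC1", "c1ccc2ccccc2c1", "CCCCO")
}

fixture_graphs <- function(smiles = fixture_smiles()) {
  lapply(smiles, parse_smiles)
}

# hand-built mol_graph (bypasses OpenBabel) for arithmetic oracles: a path
# graph of carbon atoms with single bonds
path_mol <- function(n) {
  bonds <- if (n >= 2) {
    data.frame(i = seq_len(n - 1), j = 2:n, type = 1L, dir = 1L)
  } else {
    data.frame(i = integer(0), j = integer(0), type = integer(0),
               dir = integer(0))
  }
  structure(
    list(n_atoms = as.integer(n), element = rep("C", n),
         atom_type = rep(6L, n), chirality = rep(1L, n), bonds = bonds,
         smiles = paste(rep("C", n), collapse = "")),
    class = "mol_graph"
  )
}

# random small mol_graph over a random tree plus extra edges
random_mol <- function(n, seed) {
  withr::with_seed(seed, {
    bonds <- NULL
    if (n >= 2) {
      parent <- vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1))
      bonds <- data.frame(i = pmin(parent, 2:n), j = pmax(parent, 2:n))
      extra <- if (n >= 4 && stats::runif(1) < 0.5) {
        cand <- t(utils::combn(n, 2))
        key <- paste(bonds$i, bonds$j)
        cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% key), , drop = FALSE]
        if (nrow(cand)) cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      }
      if (!is.null(extra) && length(extra)) {
        bonds <- rbind(bonds, data.frame(i = extra[1], j = extra[2]))
      }
      bonds$type <- sample(1:4, nrow(bonds), replace = TRUE)
      bonds$dir <- 1L
    } else {
      bonds <- data.frame(i = integer(0), j = integer(0), type = integer(0),
                          dir = integer(0))
    }
    structure(
      list(n_atoms = as.integer(n), element = rep("C", n),
           atom_type = sample(c(6L, 7L, 8L), n, replace = TRUE),
           chirality = rep(1L, n), bonds = bonds, smiles = "<synthetic>"),
      class = "mol_graph"
    )
  })
}

# toy DDI network on explicit drug ids
toy_network <- function(n = 6, edges = NULL) {
  ids <- sprintf("T%02d", seq_len(n))
  if (is.null(edges)) {
    edges <- data.frame(drug_id_1 = ids[c(1, 1, 2, 4)],
                        drug_id_2 = ids[c(2, 3, 3, 5)])
  }
  ddi_network(ids, edges)
}

# independent dense oracle for the symmetric normalization
oracle_norm_adj <- function(A) {
  Ahat <- A + diag(nrow(A))
  D <- diag(1 / sqrt(rowSums(Ahat)), nrow(A))
  D %*% Ahat %*% D
}

# independent dense oracle for the molecular encoder: explicit per-edge
# message loops, no shared code with the implementation
oracle_encode_molecule <- function(g, params, num_layers) {
  X <- params$atom_type_emb[g$atom_type, , drop = FALSE] +
    params$chirality_emb[g$chirality, , drop = FALSE]
  n <- g$n_atoms
  deg <- rep(1, n) # self-loop
  for (k in seq_len(nrow(g$bonds))) {
    deg[g$bonds$i[k]] <- deg[g$bonds$i[k]] + 1
    deg[g$bonds$j[k]] <- deg[g$bonds$j[k]] + 1
  }
  for (l in seq_len(num_layers)) {
    W <- params[[paste0("W", l)]]
    BT <- params[[paste0("bond_type_emb", l)]]
    BD <- params[[paste0("bond_dir_emb", l)]]
    M <- X %*% W
    out <- matrix(0, n, ncol(M))
    for (a in seq_len(n)) {
      # self loop message
      out[a, ] <- (M[a, ] + BT[5L, ] + BD[1L, ]) / deg[a]
    }
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      e <- BT[g$bonds$type[k], ] + BD[g$bonds$dir[k], ]
      out[i, ] <- out[i, ] + (M[j, ] + e) / sqrt(deg[i] * deg[j])
      out[j, ] <- out[j, ] + (M[i, ] + e) / sqrt(deg[i] * deg[j])
    }
    # column-wise batch normalization over the atoms passing through
    mu <- colMeans(out)
    v <- colMeans(out^2) - mu^2
    s <- sqrt(pmax(v, 0) + 1e-5)
    xhat <- sweep(sweep(out, 2, mu), 2, s, "/")
    bn <- sweep(xhat * rep(as.numeric(params[[paste0("bn_gamma", l)]]),
                           each = n), 2,
                as.numeric(params[[paste0("bn_beta", l)]]), "+")
    X <- if (l < num_layers) pmax(bn, 0) else bn
  }
  colMeans(X)
}

# relabel the atoms of a mol_graph by a permutation
permute_mol <- function(g, perm) {
  inv <- order(perm) # inv[old] = new position
  b <- g$bonds
  g2 <- g
  g2$atom_type <- g$atom_type[perm]
  g2$chirality <- g$chirality[perm]
  g2$element <- g$element[perm]
  g2$bonds <- data.frame(i = pmin(inv[b$i], inv[b$j]),
                         j = pmax(inv[b$i], inv[b$j]),
                         type = b$type, dir = b$dir)
  g2
}

# small, quick experiment configuration used by the training tests
quick_config <- function(...) {
  experiment_config(hidden_dim = 16, epochs = 5, batch_size = 4096,
                    patience = 5, seeds = 1L, ...)
}
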