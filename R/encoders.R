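# Graph-convolution encoders for the two views.
#
# Inter-view (molecular) encoder: categorical atom features are embedded,
# then propagated through degree-normalized graph convolutions over the bond
# graph; bond-type/direction embeddings are added into neighbor messages and
# each atom receives a self-loop message with a dedicated bond-type code.
# The molecule-level embedding is the mean over final-layer atom states.
#
# Intra-view (network) encoder: stacked ReLU(S %*% X %*% W) layers over the
# symmetric degree-normalized DDI adjacency with self-connections.

#' Symmetrically normalized adjacency with self-connections
#'
#' Computes `Deg^(-1/2) (A + I) Deg^(-1/2)` where `Deg` is the diagonal
#' row-sum of `A + I` — the propagation operator used by every graph
#' convolution in the package. Rows of isolated nodes reduce to identity
#' rows, so such nodes simply carry their own features forward.
#'
#' @param A Square symmetric 0/1 matrix with zero diagonal.
#' @return Symmetric matrix of the same dimension.
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!isSymmetric(unname(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  Ahat * tcrossprod(dinv)
}

#' One graph-convolution propagation step
#'
#' @param S Normalized adjacency (from [normalize_adjacency()]).
#' @param X Node feature matrix (nodes x features).
#' @param W Weight matrix (features x output features).
#' @param activate Apply ReLU (default `TRUE`).
#' @return `act(S %*% X %*% W)`.
#' @export
gcn_layer <- function(S, X, W, activate = TRUE) {
  if (ncol(S) != nrow(X)) stop("S and X have incompatible shapes")
  if (ncol(X) != nrow(W)) stop("X and W have incompatible shapes")
  out <- S %*% X %*% W
  if (activate) out[out < 0] <- 0
  out
}

.xavier <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Initialize molecular-encoder parameters
#'
#' Creates the trainable state of the inter-view encoder: atom-type and
#' chirality embedding tables, per-layer weight matrices, and per-layer
#' bond-type / bond-direction embedding tables (one self-loop bond code is
#' reserved so every atom hears itself).
#'
#' @param hidden_dim Hidden state width (default 300).
#' @param num_layers Number of graph-convolution layers (default 5).
#' @param seed Integer seed for the initialization draw.
#' @return Object of class `mol_encoder_params`: a named list of matrices
#'   plus `hidden_dim` / `num_layers` attributes.
#' @export
init_mol_encoder <- function(hidden_dim = 300L, num_layers = 5L, seed = 1L) {
  d <- as.integer(hidden_dim)
  L <- as.integer(num_layers)
  stopifnot(d >= 1L, L >= 1L)
  params <- withr::with_seed(seed, {
    p <- list(
      atom_type_emb = .xavier(.NUM_ATOM_TYPES, d),
      chirality_emb = .xavier(.NUM_CHIRALITY, d)
    )
    for (l in seq_len(L)) {
      p[[paste0("W", l)]] <- .xavier(d, d)
      p[[paste0("bond_type_emb", l)]] <- .xavier(.NUM_BOND_TYPES, d)
      p[[paste0("bond_dir_emb", l)]] <- .xavier(.NUM_BOND_DIRS, d)
      # per-layer batch normalization keeps activation scales stable
      # through the deep stack, during pretraining and fine-tuning alike
      p[[paste0("bn_gamma", l)]] <- matrix(1, 1L, d)
      p[[paste0("bn_beta", l)]] <- matrix(0, 1L, d)
    }
    p
  })
  structure(params, hidden_dim = d, num_layers = L,
            class = c("mol_encoder_params", "list"))
}

#' Initialize DDI-network-encoder parameters
#'
#' @param dg Embedding width shared across views (default 300).
#' @param num_layers Encoder depth (default 2, configurable to 3).
#' @param seed Integer seed.
#' @return Object of class `net_encoder_params`.
#' @export
init_net_encoder <- function(dg = 300L, num_layers = 2L, seed = 1L) {
  d <- as.integer(dg)
  L <- as.integer(num_layers)
  stopifnot(d >= 1L, L >= 1L)
  params <- withr::with_seed(seed + 1L, {
    p <- list()
    for (l in seq_len(L)) p[[paste0("W", l - 1L)]] <- .xavier(d, d)
    p
  })
  structure(params, hidden_dim = d, num_layers = L,
            class = c("net_encoder_params", "list"))
}

# ---- batched molecular graphs ----

# Flatten a list of mol_graph objects into one disjoint-union graph with
# directed edges (both bond directions plus per-atom self-loops) and the
# symmetric-normalization coefficient precomputed per directed edge.
build_mol_batch <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  sizes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  natoms <- sum(sizes)
  atom_type <- integer(natoms)
  chirality <- integer(natoms)
  src <- dst <- btype <- bdir <- integer(0)
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    off <- offsets[k]
    atom_type[off + seq_len(g$n_atoms)] <- g$atom_type
    chirality[off + seq_len(g$n_atoms)] <- g$chirality
    b <- g$bonds
    if (nrow(b)) {
      src <- c(src, off + b$i, off + b$j)
      dst <- c(dst, off + b$j, off + b$i)
      btype <- c(btype, b$type, b$type)
      bdir <- c(bdir, b$dir, b$dir)
    }
    src <- c(src, off + seq_len(g$n_atoms))
    dst <- c(dst, off + seq_len(g$n_atoms))
    btype <- c(btype, rep.int(.BOND_SELF_LOOP, g$n_atoms))
    bdir <- c(bdir, rep.int(1L, g$n_atoms))
  }
  deg <- tabulate(dst, nbins = natoms) # self-loops already included
  norm <- 1 / sqrt(deg[src] * deg[dst])
  mol_id <- rep.int(seq_along(graphs), sizes)
  list(
    n_mols = length(graphs), n_atoms = natoms,
    atom_type = atom_type, chirality = chirality,
    src = src, dst = dst, btype = btype, bdir = bdir, norm = norm,
    mol_id = mol_id, sizes = sizes
  )
}

# Tape forward pass of the molecular encoder over a batch.
# pnodes: tape nodes for mol_encoder_params entries; returns node states
# (n_atoms x d) and, if pool, molecule embeddings (n_mols x d).
.mol_forward <- function(pnodes, batch, num_layers, pool = TRUE,
                         atom_type = NULL) {
  at <- atom_type %||% batch$atom_type
  X <- ad_add(ad_gather(pnodes$atom_type_emb, at),
              ad_gather(pnodes$chirality_emb, batch$chirality))
  for (l in seq_len(num_layers)) {
    M <- ad_mm(X, pnodes[[paste0("W", l)]])
    msg <- ad_add(
      ad_gather(M, batch$src),
      ad_add(ad_gather(pnodes[[paste0("bond_type_emb", l)]], batch$btype),
             ad_gather(pnodes[[paste0("bond_dir_emb", l)]], batch$bdir))
    )
    agg <- ad_rowsum_by(ad_scale_rows(msg, batch$norm), batch$dst,
                        batch$n_atoms)
    bn <- ad_batchnorm(agg, pnodes[[paste0("bn_gamma", l)]],
                       pnodes[[paste0("bn_beta", l)]])
    X <- if (l < num_layers) ad_relu(bn) else bn
  }
  if (!pool) return(list(nodes = X))
  P <- ad_rowsum_by(X, batch$mol_id, batch$n_mols)
  H <- ad_scale_rows(P, 1 / batch$sizes)
  list(nodes = X, pooled = H)
}

#' Embed one molecule with the inter-view encoder
#'
#' Runs the graph-convolution stack over the molecule's bond graph and
#' mean-pools the final atom states into a single molecule-level vector.
#'
#' @param g A `mol_graph` from [parse_smiles()].
#' @param params Encoder parameters from [init_mol_encoder()] (possibly
#'   pretrained via [pretrain()]).
#' @return Numeric vector of length `hidden_dim`.
#' @export
encode_molecule <- function(g, params) {
  stopifnot(is_mol_graph(g), inherits(params, "mol_encoder_params"))
  if (g$n_atoms < 1L) stop("cannot encode an empty molecular graph")
  encode_molecules(list(g), params)[1L, ]
}

#' Embed a list of molecules (rows align with the input order)
#'
#' Each layer batch-normalizes over all atoms in the encoded batch, so a
#' molecule's embedding depends (weakly) on which molecules it is encoded
#' with; encode the full drug set in one call — as every routine in this
#' package does — for consistent embeddings.
#'
#' @param graphs List of `mol_graph` objects.
#' @param params Parameters from [init_mol_encoder()].
#' @return Matrix `length(graphs) x hidden_dim`.
#' @export
encode_molecules <- function(graphs, params) {
  stopifnot(inherits(params, "mol_encoder_params"))
  batch <- build_mol_batch(graphs)
  tape <- ad_tape()
  pnodes <- ad_consts_in(tape, params)
  fw <- .mol_forward(pnodes, batch, attr(params, "num_layers"), pool = TRUE)
  unname(fw$pooled$value)
}

# Tape forward of the DDI-network encoder: stacked ReLU(S X W) layers.
.net_forward <- function(pnodes, Snode, Hnode, num_layers) {
  X <- Hnode
  for (l in seq_len(num_layers)) {
    X <- ad_relu(ad_mm(ad_mm(Snode, X), pnodes[[paste0("W", l - 1L)]]))
  }
  X
}

#' Encode drugs over the DDI network (intra-view)
#'
#' Propagates the molecule-level embeddings `H` over the normalized DDI
#' adjacency, producing per-drug intra-view embeddings that blend a drug's
#' own structure with the structures of its known interaction partners.
#' During training only train-split links should enter the adjacency; pass
#' them via `links`.
#'
#' @param H Matrix `n x dg` of inter-view embeddings, rows aligned with
#'   `network$drug_ids`.
#' @param network A [ddi_network()].
#' @param params Parameters from [init_net_encoder()].
#' @param links Optional data frame (`i`, `j`) restricting which links form
#'   the adjacency (default: all positive links in the network).
#' @return Matrix `n x dg` of intra-view embeddings.
#' @export
encode_network <- function(H, network, params, links = NULL) {
  stopifnot(inherits(params, "net_encoder_params"))
  H <- as.matrix(H)
  if (nrow(H) != network$n) stop("H rows must align with network drugs")
  if (ncol(H) != attr(params, "hidden_dim")) {
    stop("H columns do not match encoder width")
  }
  S <- normalize_adjacency(adjacency_matrix(network, links))
  tape <- ad_tape()
  pnodes <- ad_consts_in(tape, params)
  out <- .net_forward(pnodes, ad_const(tape, S), ad_const(tape, H),
                      attr(params, "num_layers"))
  unname(out$value)
}

# ---- checkpoints ----

#' Save / load encoder checkpoints
#'
#' Checkpoints are versioned JSON files holding every weight matrix plus the
#' featurization vocabulary sizes, so a pretrained encoder can be reloaded
#' into a fresh session and produce bit-identical embeddings.
#'
#' @param params A `mol_encoder_params` or `net_encoder_params` object, or a
#'   plain named list of matrices.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the parameter object.
#' @export
save_checkpoint <- function(params, path) {
  payload <- list(
    format = "mvddi-checkpoint",
    version = 1L,
    class = class(params)[1L],
    hidden_dim = attr(params, "hidden_dim"),
    num_layers = attr(params, "num_layers"),
    vocab = list(atom_types = .NUM_ATOM_TYPES, chirality = .NUM_CHIRALITY,
                 bond_types = .NUM_BOND_TYPES, bond_dirs = .NUM_BOND_DIRS),
    # %.17g round-trips IEEE doubles exactly, so reloaded encoders are
    # bit-identical to the saved ones
    weights = lapply(unclass(params), function(m) {
      list(dim = dim(as.matrix(m)), data = sprintf("%.17g", as.numeric(m)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mvddi-checkpoint")) {
    stop("not an mvddi checkpoint: ", path)
  }
  weights <- lapply(payload$weights, function(w) {
    matrix(as.numeric(w$data), w$dim[1L], w$dim[2L])
  })
  cls <- payload$class
  structure(weights,
            hidden_dim = as.integer(payload$hidden_dim),
            num_layers = as.integer(payload$num_layers),
            class = if (cls %in% c("mol_encoder_params",
                                   "net_encoder_params")) {
              c(cls, "list")
            } else "list")
}
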