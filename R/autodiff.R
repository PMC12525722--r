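# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every trainable component in the package (molecular-graph encoder,
# DDI-network encoder, link-prediction heads, self-supervised pretraining
# losses, the composite training objective) expresses its forward pass as a
# graph of the operations below; gradients are obtained by walking the tape
# backwards. Nodes are created in topological order by construction, so the
# reverse sweep is a single pass over the tape.
#
# Values are numeric matrices (scalars are 1x1). Only nodes reachable from a
# parameter (`needs_grad`) accumulate gradients.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

.ad_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

.ad_new <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$needs_grad <- any(vapply(parents, function(p) p$needs_grad, logical(1)))
  .ad_push(tape, node)
}

#' @noRd
ad_param <- function(tape, value) {
  node <- .ad_new(tape, as.matrix(value))
  node$needs_grad <- TRUE
  node$is_param <- TRUE
  node$tape <- tape
  node
}

#' @noRd
ad_const <- function(tape, value) {
  node <- .ad_new(tape, as.matrix(value))
  node$tape <- tape
  node
}

.ad_accum <- function(node, g) {
  if (!node$needs_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# ---- arithmetic ----

ad_mm <- function(a, b) {
  .ad_op2(a, b, a$value %*% b$value, function(node) {
    g <- node$grad
    .ad_accum(a, g %*% t(b$value))
    .ad_accum(b, crossprod(a$value, g))
  })
}

# all ops share one tape per forward pass; it is threaded through the node
# environments to keep call sites terse.
.ad_op2 <- function(a, b, value, backfn) {
  tape <- a$tape %||% b$tape
  node <- .ad_new(tape, value, parents = list(a, b))
  node$tape <- tape
  node$backward <- backfn
  node
}

.ad_op1 <- function(a, value, backfn) {
  node <- .ad_new(a$tape, value, parents = list(a))
  node$tape <- a$tape
  node$backward <- backfn
  node
}

`%||%` <- function(x, y) if (is.null(x)) y else x

ad_add <- function(a, b) {
  av <- a$value; bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    # row-vector broadcast (bias terms)
    value <- sweep(av, 2L, as.numeric(bv), `+`)
    .ad_op2(a, b, value, function(node) {
      g <- node$grad
      .ad_accum(a, g)
      .ad_accum(b, matrix(colSums(g), 1L))
    })
  } else {
    .ad_op2(a, b, av + bv, function(node) {
      g <- node$grad
      .ad_accum(a, g)
      .ad_accum(b, g)
    })
  }
}

ad_sub <- function(a, b) {
  av <- a$value; bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    value <- sweep(av, 2L, as.numeric(bv), `-`)
    .ad_op2(a, b, value, function(node) {
      g <- node$grad
      .ad_accum(a, g)
      .ad_accum(b, matrix(-colSums(g), 1L))
    })
  } else {
    .ad_op2(a, b, av - bv, function(node) {
      g <- node$grad
      .ad_accum(a, g)
      .ad_accum(b, -g)
    })
  }
}

ad_mul <- function(a, b) {
  .ad_op2(a, b, a$value * b$value, function(node) {
    g <- node$grad
    .ad_accum(a, g * b$value)
    .ad_accum(b, g * a$value)
  })
}

ad_scale <- function(a, s) {
  .ad_op1(a, a$value * s, function(node) .ad_accum(a, node$grad * s))
}

ad_relu <- function(a) {
  mask <- a$value > 0
  .ad_op1(a, a$value * mask, function(node) .ad_accum(a, node$grad * mask))
}

ad_pow <- function(a, k) {
  .ad_op1(a, a$value^k, function(node) {
    .ad_accum(a, node$grad * k * a$value^(k - 1))
  })
}

# ---- indexing / aggregation ----

# rows of `a` selected by integer index (embedding lookup / gather)
ad_gather <- function(a, idx) {
  idx <- as.integer(idx)
  .ad_op1(a, a$value[idx, , drop = FALSE], function(node) {
    g <- node$grad
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nrow(a$value), ncol(a$value))
    full[as.integer(rownames(acc)), ] <- acc
    .ad_accum(a, full)
  })
}

# out[k, ] = sum of rows of `a` whose group == k, for k in 1..ngroups
ad_rowsum_by <- function(a, group, ngroups) {
  group <- as.integer(group)
  acc <- rowsum(a$value, group = group)
  value <- matrix(0, ngroups, ncol(a$value))
  value[as.integer(rownames(acc)), ] <- acc
  .ad_op1(a, value, function(node) {
    .ad_accum(a, node$grad[group, , drop = FALSE])
  })
}

# rows of `a` scaled by a fixed numeric vector v (length nrow(a))
ad_scale_rows <- function(a, v) {
  v <- as.numeric(v)
  .ad_op1(a, a$value * v, function(node) .ad_accum(a, node$grad * v))
}

ad_colmeans <- function(a) {
  n <- nrow(a$value)
  .ad_op1(a, matrix(colMeans(a$value), 1L), function(node) {
    .ad_accum(a, matrix(rep(node$grad / n, each = n), n))
  })
}

ad_sum <- function(a) {
  .ad_op1(a, matrix(sum(a$value), 1L, 1L), function(node) {
    g <- as.numeric(node$grad)
    .ad_accum(a, matrix(g, nrow(a$value), ncol(a$value)))
  })
}

# rowwise dot products of two equally-shaped matrices -> n x 1
ad_rows_dot <- function(a, b) {
  .ad_op2(a, b, matrix(rowSums(a$value * b$value), ncol = 1L), function(node) {
    g <- as.numeric(node$grad)
    .ad_accum(a, b$value * g)
    .ad_accum(b, a$value * g)
  })
}

# ---- nonlinear heads ----

ad_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  .ad_op1(a, p, function(node) {
    g <- node$grad
    .ad_accum(a, p * (g - rowSums(g * p)))
  })
}

ad_log <- function(a, eps = 1e-12) {
  clamped <- pmax(a$value, eps)
  .ad_op1(a, log(clamped), function(node) .ad_accum(a, node$grad / clamped))
}

# sum over rows of the 2-class (or C-class) cross-entropy of row-softmaxed
# logits against integer class labels y in 1..C
ad_ce_logits <- function(logits, y) {
  y <- as.integer(y)
  z <- logits$value - apply(logits$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_along(y), y)]
  value <- matrix(sum(-log(pmax(picked, 1e-300))), 1L, 1L)
  .ad_op1(logits, value, function(node) {
    g <- as.numeric(node$grad)
    d <- p
    d[cbind(seq_along(y), y)] <- d[cbind(seq_along(y), y)] - 1
    .ad_accum(logits, d * g)
  })
}

# sum over elements of binary cross-entropy on sigmoid(score) vs y in {0,1},
# computed in the numerically stable softplus form
ad_bce_logits <- function(scores, y) {
  s <- as.numeric(scores$value)
  y <- as.numeric(y)
  value <- matrix(sum(pmax(s, 0) - s * y + log1p(exp(-abs(s)))), 1L, 1L)
  .ad_op1(scores, value, function(node) {
    g <- as.numeric(node$grad)
    sig <- 1 / (1 + exp(-s))
    .ad_accum(scores, matrix((sig - y) * g, nrow(scores$value), 1L))
  })
}

# column-wise batch normalization with trainable scale/shift row vectors;
# statistics are those of the rows passing through (biased variance)
ad_batchnorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  s <- sqrt(pmax(v, 0) + eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, s, `/`)
  value <- sweep(xhat * rep(as.numeric(gamma$value), each = n), 2L,
                 as.numeric(beta$value), `+`)
  node <- .ad_new(a$tape, value, parents = list(a, gamma, beta))
  node$tape <- a$tape
  node$backward <- function(node) {
    g <- node$grad
    .ad_accum(gamma, matrix(colSums(g * xhat), 1L))
    .ad_accum(beta, matrix(colSums(g), 1L))
    if (a$needs_grad) {
      dxhat <- g * rep(as.numeric(gamma$value), each = n)
      t1 <- sweep(dxhat * n, 2L, colSums(dxhat))
      t2 <- xhat * rep(colSums(dxhat * xhat), each = n)
      .ad_accum(a, sweep(t1 - t2, 2L, n * s, `/`))
    }
  }
  node
}

# Euclidean norm of the difference of two row vectors (or matrices)
ad_l2diff <- function(a, b) {
  d <- a$value - b$value
  nrm <- sqrt(sum(d^2))
  .ad_op2(a, b, matrix(nrm, 1L, 1L), function(node) {
    g <- as.numeric(node$grad)
    if (nrm > 1e-12) {
      .ad_accum(a, g * d / nrm)
      .ad_accum(b, -g * d / nrm)
    }
  })
}

# sum of an arbitrary list of scalar nodes
ad_addn <- function(nodes) {
  stopifnot(length(nodes) >= 1L)
  out <- nodes[[1L]]
  if (length(nodes) > 1L) {
    for (k in 2L:length(nodes)) out <- ad_add(out, nodes[[k]])
  }
  out
}

#' @noRd
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward) || !node$needs_grad) next
    node$backward(node)
  }
  invisible(NULL)
}

# Wrap a flat named list of matrices as parameter nodes on one tape.
ad_params_in <- function(tape, params) {
  out <- lapply(params, function(p) {
    node <- ad_param(tape, p)
    node$tape <- tape
    node
  })
  out
}

ad_consts_in <- function(tape, params) {
  lapply(params, function(p) {
    node <- ad_const(tape, p)
    node$tape <- tape
    node
  })
}

ad_grads_out <- function(pnodes) {
  lapply(pnodes, function(p) {
    if (is.null(p$grad)) matrix(0, nrow(p$value), ncol(p$value)) else p$grad
  })
}

# ---- Adam optimiser over flat named lists of matrices ----

adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) array(0, dim(as.matrix(p)))),
    v = lapply(params, function(p) array(0, dim(as.matrix(p))))
  )
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
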