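# The composite training objective: supervised cross-entropy on both
# predictor heads, output-space matching (KL divergence between the two
# heads' predictive distributions per link), and feature-space matching (a
# central moment discrepancy between the intra-view and inter-view embedding
# distributions, moments up to order K = 5).

.EPS <- 1e-12

#' Supervised loss over both predictor heads
#'
#' Sum over links of `CE(p, y) + CE(q, y)` where `CE(r, y) = -ln r[y]`, `p`
#' is the main head's probability pair and `q` the auxiliary head's.
#' Probabilities of exactly zero at the true class are clamped at 1e-12.
#'
#' @param p,q Matrices `m x 2` of class-probability pairs (rows on the
#'   2-simplex).
#' @param y Integer vector of true labels in \{0, 1\}.
#' @return Scalar loss (a sum, not a mean).
#' @export
supervised_loss <- function(p, q, y) {
  p <- rbind(p); q <- rbind(q)
  y <- as.integer(y)
  stopifnot(ncol(p) == 2L, ncol(q) == 2L,
            nrow(p) == length(y), nrow(q) == length(y),
            all(y %in% c(0L, 1L)))
  idx <- cbind(seq_along(y), y + 1L)
  sum(-log(pmax(p[idx], .EPS))) + sum(-log(pmax(q[idx], .EPS)))
}

#' Output-space matching loss (KL divergence between heads)
#'
#' Sum over links of `KL(p || q)` in natural log, with the convention
#' `0 * ln 0 = 0` and epsilon clamping of `q` where `p > 0`.
#'
#' @param p,q Matrices `m x 2` of probability pairs.
#' @return Scalar loss (non-negative).
#' @export
output_matching_loss <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  stopifnot(dim(p)[1] == dim(q)[1], ncol(p) == 2L, ncol(q) == 2L)
  terms <- ifelse(p > 0, p * (log(pmax(p, .EPS)) - log(pmax(q, .EPS))), 0)
  sum(terms)
}

#' Component-wise k-th central moment of a set of vectors
#'
#' @param X Matrix with one vector per row.
#' @param k Moment order (`k >= 1`; `k = 1` gives a zero vector by
#'   definition of central moments).
#' @return Numeric vector of length `ncol(X)`.
#' @export
central_moments <- function(X, k) {
  X <- rbind(X)
  if (nrow(X) < 1L) stop("need at least one vector")
  stopifnot(k >= 1)
  mu <- colMeans(X)
  colMeans(sweep(X, 2L, mu)^k)
}

#' Central moment discrepancy between two embedding distributions
#'
#' `||E(D) - E(H)||_2 + sum_{k=2}^K ||C_k(D) - C_k(H)||_2` with `E` the
#' component-wise mean and `C_k` the component-wise k-th central moment over
#' rows. Symmetric, non-negative, and zero when all moments up to `K`
#' coincide. This is the feature-space matching regularizer that pulls the
#' intra-view embedding distribution toward the (pretrained) molecular one.
#'
#' @param D,H Matrices with equal column counts (rows = drugs).
#' @param K Highest moment order (default 5).
#' @return Scalar.
#' @export
cmd_loss <- function(D, H, K = 5L) {
  D <- rbind(D); H <- rbind(H)
  if (ncol(D) != ncol(H)) stop("column counts differ")
  stopifnot(nrow(D) >= 1L, nrow(H) >= 1L, K >= 1L)
  out <- sqrt(sum((colMeans(D) - colMeans(H))^2))
  if (K >= 2L) {
    for (k in 2:K) {
      out <- out + sqrt(sum((central_moments(D, k) - central_moments(H, k))^2))
    }
  }
  out
}

#' Combine the loss components
#'
#' `total = Ls + alpha * Lom + gamma * Lfm`, with the defaults alpha = 1 and
#' gamma = 2 used throughout the experiments.
#'
#' @param Ls,Lom,Lfm Scalar loss components.
#' @param alpha Weight of the output-space matching term (default 1).
#' @param gamma Weight of the feature-space matching term (default 2).
#' @param K Moment order recorded in the breakdown (default 5).
#' @return Object of class `loss_breakdown`: list with `Ls`, `Lom`, `Lfm`,
#'   `total`, `alpha`, `gamma`, `K`.
#' @export
total_loss <- function(Ls, Lom, Lfm, alpha = 1, gamma = 2, K = 5L) {
  if (alpha < 0 || gamma < 0) stop("loss weights must be non-negative")
  stopifnot(is.finite(Ls), is.finite(Lom), is.finite(Lfm))
  structure(
    list(Ls = Ls, Lom = Lom, Lfm = Lfm,
         total = Ls + alpha * Lom + gamma * Lfm,
         alpha = alpha, gamma = gamma, K = as.integer(K)),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total %.6g = Ls %.6g + %g * Lom %.6g + %g * Lfm %.6g\n",
    x$total, x$Ls, x$alpha, x$Lom, x$gamma, x$Lfm))
  invisible(x)
}

# ---- tape versions used by the training loop ----

# KL(p || q) summed over rows, from the two logit nodes
.ad_kl_from_logits <- function(logits_p, logits_q) {
  p <- ad_softmax_rows(logits_p)
  q <- ad_softmax_rows(logits_q)
  ad_sum(ad_mul(p, ad_sub(ad_log(p), ad_log(q))))
}

# CMD between two embedding nodes, moments to order K
.ad_cmd <- function(Dnode, Hnode, K = 5L) {
  terms <- list(ad_l2diff(ad_colmeans(Dnode), ad_colmeans(Hnode)))
  if (K >= 2L) {
    muD <- ad_colmeans(Dnode)
    muH <- ad_colmeans(Hnode)
    cD <- ad_sub(Dnode, muD)
    cH <- ad_sub(Hnode, muH)
    for (k in 2:K) {
      terms[[length(terms) + 1L]] <-
        ad_l2diff(ad_colmeans(ad_pow(cD, k)), ad_colmeans(ad_pow(cH, k)))
    }
  }
  ad_addn(terms)
}
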