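# Link prediction heads.
#
# The main predictor consumes the fused intra-view pair embedding through a
# two-layer fully connected network; the auxiliary predictor consumes the
# fused inter-view (molecular) pair embedding through a single linear layer.
# Both emit two logits normalized to a probability pair, so an interaction
# probability and its complement always sum to one and the two heads can be
# compared with a KL divergence during training.

#' Initialize link-predictor parameters
#'
#' @param dg Embedding width of the drug vectors.
#' @param hidden Width of the main head's hidden layer (default `dg`).
#' @param seed Integer seed.
#' @return Object of class `predictor_params` holding `W_I`, `b_I`, `W_k`,
#'   `b_k` (main two-layer head) and `aux_W`, `aux_b` (auxiliary linear
#'   head); both heads output 2 logits.
#' @export
init_predictor <- function(dg, hidden = dg, seed = 1L) {
  dg <- as.integer(dg); hidden <- as.integer(hidden)
  params <- withr::with_seed(seed + 2L, list(
    W_I = .xavier(dg, hidden),
    b_I = matrix(0, 1L, hidden),
    W_k = .xavier(hidden, 2L),
    b_k = matrix(0, 1L, 2L),
    aux_W = .xavier(dg, 2L),
    aux_b = matrix(0, 1L, 2L)
  ))
  structure(params, dg = dg, hidden = hidden,
            class = c("predictor_params", "list"))
}

#' Fuse two drug embeddings into a link embedding
#'
#' The element-wise product of the two drug vectors; symmetric in its
#' arguments, as required for an undirected interaction.
#'
#' @param d_i,d_j Numeric vectors of equal length.
#' @return Numeric vector of the same length.
#' @examples
#' fuse(c(1, 2), c(3, 4)) # c(3, 8)
#' @export
fuse <- function(d_i, d_j) {
  if (length(d_i) != length(d_j)) stop("embedding lengths differ")
  d_i * d_j
}

.softmax2 <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

#' Main interaction probability from a fused link embedding
#'
#' `hidden = ReLU(W_I i + b_I)`, two logits `W_k hidden + b_k`, normalized
#' exponentials.
#'
#' @param I_ij Fused link embedding ([fuse()] of two intra-view vectors).
#' @param params A [init_predictor()] object.
#' @return Length-2 probability vector `(no interaction, interaction)`.
#' @export
predict_main <- function(I_ij, params) {
  stopifnot(inherits(params, "predictor_params"))
  if (!all(is.finite(I_ij))) stop("non-finite link embedding")
  hidden <- pmax(as.numeric(I_ij %*% params$W_I) + as.numeric(params$b_I), 0)
  logits <- as.numeric(hidden %*% params$W_k) + as.numeric(params$b_k)
  .softmax2(logits)
}

#' Auxiliary interaction probability from the molecular view
#'
#' The inter-view pair is fused by element-wise product (mirroring the main
#' path) and passed through one linear layer to 2 logits.
#'
#' @param h_i,h_j Inter-view (molecular) embeddings of the two drugs.
#' @param params A [init_predictor()] object.
#' @return Length-2 probability vector.
#' @export
predict_aux <- function(h_i, h_j, params) {
  stopifnot(inherits(params, "predictor_params"))
  v <- fuse(h_i, h_j)
  if (!all(is.finite(v))) stop("non-finite embeddings")
  logits <- as.numeric(v %*% params$aux_W) + as.numeric(params$aux_b)
  .softmax2(logits)
}

# tape versions used inside the training loop (rows = links in the batch)
.predict_main_logits <- function(pnodes, Inode) {
  hidden <- ad_relu(ad_add(ad_mm(Inode, pnodes$W_I), pnodes$b_I))
  ad_add(ad_mm(hidden, pnodes$W_k), pnodes$b_k)
}

.predict_aux_logits <- function(pnodes, Hpair) {
  ad_add(ad_mm(Hpair, pnodes$aux_W), pnodes$aux_b)
}
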