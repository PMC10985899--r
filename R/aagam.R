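# Adaptive cross-drug attention aggregation.
#
# Each atom of one drug is scored against every atom of the partner drug:
# the key projection of the self drug meets the query projection of the
# partner in a tanh-squashed score matrix; row sums, softmax-normalized over
# the self drug's atoms, give one attention weight per atom. The graph-level
# embedding is the weighted sum of value-projected atom embeddings plus a
# residual mean, layer-normalized. The per-atom weights double as the
# substructure-importance scores exported in attention reports.

#' Initialize cross-attention aggregation parameters
#'
#' Three square projection matrices on the embedding width: keys and values
#' belong to the drug being pooled, queries to its partner. One parameter
#' set is shared between the A-against-B and B-against-A directions.
#'
#' @param dim Node-embedding width.
#' @return An `aagam_params` list with `Wk`, `Wq`, `Wv`.
#' @export
init_aagam_params <- function(dim) {
  stopifnot(is_count(dim))
  s <- sqrt(6 / (2 * dim))
  rnd <- function() matrix(stats::runif(dim * dim, -s, s), dim, dim)
  structure(list(Wk = rnd(), Wq = rnd(), Wv = rnd()), class = "aagam_params")
}

#' Cross-drug attention scores for one drug of a pair
#'
#' Scores every atom of the self drug against all atoms of the partner drug
#' and softmax-normalizes over the self drug's atoms: the result is a
#' strictly positive per-atom weight vector summing to 1, interpreted as the
#' importance of each substructure for the pair.
#'
#' @param E_self Node embeddings of the drug being scored (atoms x width).
#' @param E_other Node embeddings of the partner drug (same width).
#' @param params An `aagam_params` object.
#' @return Numeric vector of length `nrow(E_self)` summing to 1.
#' @export
cross_attention_scores <- function(E_self, E_other, params) {
  E_self <- as.matrix(E_self); E_other <- as.matrix(E_other)
  d <- ncol(E_self)
  if (ncol(E_other) != d)
    stop_config("embedding widths differ: %d vs %d", d, ncol(E_other))
  if (d != ncol(params$Wk))
    stop_config("params expect width %d, embeddings have %d", ncol(params$Wk), d)
  K <- E_self %*% params$Wk
  Q <- E_other %*% params$Wq
  r <- rowSums(tanh(K %*% t(Q)))
  softmax_vec(r)
}

#' Attention-weighted pooling of one drug's atoms
#'
#' Collapses per-atom embeddings into one graph-level vector: each atom's
#' value projection is weighted by its attention score and summed.
#'
#' @param E_self Node embeddings (atoms x width).
#' @param scores Normalized per-atom attention scores.
#' @param params An `aagam_params` object (only `Wv` is used).
#' @return Numeric vector of the embedding width.
#' @export
attention_pool <- function(E_self, scores, params) {
  E_self <- as.matrix(E_self)
  if (length(scores) != nrow(E_self))
    stop_config("scores length %d != %d atoms", length(scores), nrow(E_self))
  V <- E_self %*% params$Wv
  drop(crossprod(V, scores))
}

#' Graph-level readout with residual mean and normalization
#'
#' The final graph representation is the layer normalization (feature-axis
#' mean 0, variance 1; no learnable affine) of the atom-mean embedding plus
#' the attention-pooled vector. An all-zero input maps to the zero vector.
#'
#' @param E_self Node embeddings (atoms x width).
#' @param g Attention-pooled vector from [attention_pool()].
#' @return Numeric vector of the embedding width.
#' @export
graph_readout <- function(E_self, g) {
  E_self <- as.matrix(E_self)
  if (length(g) != ncol(E_self))
    stop_config("pooled width %d != embedding width %d", length(g), ncol(E_self))
  layer_norm(colMeans(E_self) + g)$out
}

# One direction of the aggregation with cache (self pooled against other).
aagam_dir_fwd <- function(E_self, E_other, params) {
  K <- E_self %*% params$Wk
  Q <- E_other %*% params$Wq
  Tm <- tanh(K %*% t(Q))
  r <- rowSums(Tm)
  s <- softmax_vec(r)
  V <- E_self %*% params$Wv
  g <- drop(crossprod(V, s))
  ln <- layer_norm(colMeans(E_self) + g)
  list(G = ln$out, scores = s,
       cache = list(E_self = E_self, E_other = E_other, K = K, Q = Q,
                    Tm = Tm, s = s, V = V, ln = ln, params = params))
}

# Backward of one direction: dG -> gradients for both embedding matrices and
# the (shared) projections.
aagam_dir_bwd <- function(dG, cache) {
  p <- cache$params
  E_self <- cache$E_self; E_other <- cache$E_other
  n_self <- nrow(E_self)
  du <- layer_norm_grad(dG, cache$ln)
  dE_self <- matrix(du / n_self, n_self, length(du), byrow = TRUE)  # mean term
  dg <- du
  ds <- drop(cache$V %*% dg)
  dV <- outer(cache$s, dg)
  dWv <- crossprod(E_self, dV)
  dE_self <- dE_self + dV %*% t(p$Wv)
  s <- cache$s
  dr <- s * (ds - sum(s * ds))
  dT <- matrix(dr, n_self, nrow(E_other))
  dM <- dT * (1 - cache$Tm^2)
  dK <- dM %*% cache$Q
  dQ <- crossprod(dM, cache$K)
  dWk <- crossprod(E_self, dK)
  dWq <- crossprod(E_other, dQ)
  dE_self <- dE_self + dK %*% t(p$Wk)
  dE_other <- dQ %*% t(p$Wq)
  list(dE_self = dE_self, dE_other = dE_other,
       dparams = list(Wk = dWk, Wq = dWq, Wv = dWv))
}

# Both directions of a drug pair with tied parameters.
aagam_pair_fwd <- function(E_A, E_B, params) {
  a <- aagam_dir_fwd(E_A, E_B, params)
  b <- aagam_dir_fwd(E_B, E_A, params)
  list(G_x = a$G, G_y = b$G, scores_A = a$scores, scores_B = b$scores,
       cache = list(a = a$cache, b = b$cache))
}

aagam_pair_bwd <- function(dG_x, dG_y, cache) {
  ba <- aagam_dir_bwd(dG_x, cache$a)
  bb <- aagam_dir_bwd(dG_y, cache$b)
  list(dE_A = ba$dE_self + bb$dE_other,
       dE_B = ba$dE_other + bb$dE_self,
       dparams = par_zip(ba$dparams, bb$dparams, `+`))
}
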