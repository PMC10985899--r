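# Classification head (2-layer MLP + softmax over {antagonistic, synergistic})
# and the dual-pass training objective: each sample is forwarded twice under
# independent dropout; the loss is the mean of both cross-entropies plus a
# symmetric Kullback-Leibler consistency term between the two predictive
# distributions.

#' Binary cross-entropy
#'
#' `-[y log(p) + (1 - y) log(1 - p)]` with eps-clamped logarithms, so the
#' loss is finite at the endpoints. With a two-class softmax head this is
#' identical to categorical cross-entropy on the synergy-class probability.
#'
#' @param prob Predicted probability of the positive (synergistic) class;
#'   vectorized.
#' @param label 0/1 true labels.
#' @param eps Numeric floor for the logarithms.
#' @return Numeric vector of losses.
#' @export
#' @examples
#' cross_entropy(0.5, 1)  # log(2)
cross_entropy <- function(prob, label, eps = 1e-12) {
  stopifnot(all(prob >= 0 & prob <= 1, na.rm = TRUE), eps > 0)
  -(label * log(pmax(prob, eps)) + (1 - label) * log(pmax(1 - prob, eps)))
}

#' Kullback-Leibler divergence between class distributions
#'
#' `KL(p || q) = sum p (log p - log q)`, eps-clamped; non-negative, zero iff
#' the distributions coincide (up to eps effects). Rows of matrices are
#' treated as independent distributions.
#'
#' @param p,q Probability vectors (or matrices with one distribution per
#'   row) of matching shape.
#' @param eps Numeric floor for the logarithms.
#' @return Scalar, or one value per row.
#' @export
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))  # -> log(2) as eps -> 0
kl_divergence <- function(p, q, eps = 1e-12) {
  stopifnot(eps > 0)
  if (is.null(dim(p))) {
    sum(p * (log(pmax(p, eps)) - log(pmax(q, eps))))
  } else {
    rowSums(p * (log(pmax(p, eps)) - log(pmax(q, eps))))
  }
}

#' Initialize the classification head
#'
#' A two-layer perceptron (relu hidden layer, then a linear map to two
#' logits) applied after the fusion controller.
#'
#' @param in_dim Fused width entering the head.
#' @param hidden Hidden width.
#' @return A `head_params` list (`W1`, `b1`, `W2`, `b2`).
#' @export
init_head_params <- function(in_dim, hidden) {
  s1 <- sqrt(6 / (in_dim + hidden))
  s2 <- sqrt(6 / (hidden + 2))
  structure(list(
    W1 = matrix(stats::runif(in_dim * hidden, -s1, s1), in_dim, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::runif(hidden * 2L, -s2, s2), hidden, 2L),
    b2 = rep(0, 2L)), class = "head_params")
}

# Head forward on a batch (rows); optional dropout mask on the hidden layer.
head_fwd <- function(X, params, drop_mask = NULL) {
  H_pre <- X %*% params$W1 + rep(params$b1, each = nrow(X))
  H <- relu(H_pre)
  if (!is.null(drop_mask)) H <- H * drop_mask
  Z <- H %*% params$W2 + rep(params$b2, each = nrow(X))
  P <- softmax_rows(Z)
  list(P = P, Z = Z,
       cache = list(X = X, H_pre = H_pre, H = H, drop_mask = drop_mask,
                    params = params))
}

head_bwd <- function(dZ, cache) {
  p <- cache$params
  dW2 <- crossprod(cache$H, dZ)
  db2 <- colSums(dZ)
  dH <- dZ %*% t(p$W2)
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  dH_pre <- dH * (cache$H_pre > 0)
  dW1 <- crossprod(cache$X, dH_pre)
  db1 <- colSums(dH_pre)
  dX <- dH_pre %*% t(p$W1)
  list(dX = dX, dparams = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Dual-pass objective on two softmax outputs of the same batch:
#   L_i = 1/2 [ CE(P1_i) + CE(P2_i) + alpha (KL(P1||P2) + KL(P2||P1))_i ]
# Returns the mean loss and its gradients with respect to both logit
# matrices (and alpha), derived through the softmax.
dual_loss_grads <- function(P1, P2, labels, alpha, eps = 1e-12) {
  B <- nrow(P1)
  Y <- cbind(1 - labels, labels)  # one-hot over (antagonistic, synergistic)
  ce1 <- cross_entropy(P1[, 2L], labels, eps)
  ce2 <- cross_entropy(P2[, 2L], labels, eps)
  kl12 <- kl_divergence(P1, P2, eps)
  kl21 <- kl_divergence(P2, P1, eps)
  loss <- mean(0.5 * (ce1 + ce2 + alpha * (kl12 + kl21)))
  L1 <- log(pmax(P1, eps)); L2 <- log(pmax(P2, eps))
  dZ1 <- 0.5 / B * ((P1 - Y) +
    alpha * (P1 * (L1 - L2 - kl12) + (P1 - P2)))
  dZ2 <- 0.5 / B * ((P2 - Y) +
    alpha * (P2 * (L2 - L1 - kl21) + (P2 - P1)))
  dalpha <- mean(0.5 * (kl12 + kl21))
  list(loss = loss, dZ1 = dZ1, dZ2 = dZ2, dalpha = dalpha,
       ce = mean(0.5 * (ce1 + ce2)), kl = dalpha)
}
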