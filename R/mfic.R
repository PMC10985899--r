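# Gated multi-source feature interaction controller: a highway-style layer
# blending a relu-transformed and a linearly transformed copy of the fused
# drug-drug-cell vector under a sigmoid gate, stacked to a configurable
# depth. Width is preserved throughout.

#' Initialize the gated fusion controller
#'
#' Each of `depth` layers carries three width-preserving affine maps: the
#' gate (sigmoid), the nonlinear branch (relu) and the linear carry branch.
#' The gate bias starts negative so early training favors the carry path.
#'
#' @param dim Fused vector width (3 x embedding width in the full model).
#' @param depth Number of stacked layers.
#' @param gate_bias_init Initial gate bias (default -1).
#' @param identity_q If `TRUE` the carry branch is the identity instead of a
#'   learnable affine (classic highway carry).
#' @param param_free_gate If `TRUE` the gate is `sigmoid(F)` with no
#'   parameters (ablation mode).
#' @return An `mfic_params` object.
#' @export
init_mfic_params <- function(dim, depth = 2L, gate_bias_init = -1,
                             identity_q = FALSE, param_free_gate = FALSE) {
  stopifnot(is_count(dim), is_count(depth))
  s <- sqrt(6 / (2 * dim))
  aff <- function(bias0 = 0) list(
    W = matrix(stats::runif(dim * dim, -s, s), dim, dim),
    b = rep(bias0, dim))
  layers <- lapply(seq_len(depth), function(i) {
    l <- list(nonlinear = aff())
    if (!param_free_gate) l$gate <- aff(gate_bias_init)
    if (!identity_q) l$linear <- aff()
    l
  })
  structure(list(layers = layers, dim = dim, depth = depth,
                 identity_q = identity_q, param_free_gate = param_free_gate),
            class = "mfic_params")
}

.mfic_layer_fwd <- function(X, layer, opts) {
  gate_pre <- if (opts$param_free_gate) X
              else X %*% layer$gate$W + rep(layer$gate$b, each = nrow(X))
  G <- sigmoid(gate_pre)
  w_pre <- X %*% layer$nonlinear$W + rep(layer$nonlinear$b, each = nrow(X))
  w <- relu(w_pre)
  q <- if (opts$identity_q) X
       else X %*% layer$linear$W + rep(layer$linear$b, each = nrow(X))
  Y <- G * w + (1 - G) * q
  list(out = Y, cache = list(X = X, G = G, w_pre = w_pre, w = w, q = q,
                             layer = layer, opts = opts))
}

.mfic_layer_bwd <- function(dY, cache) {
  layer <- cache$layer; opts <- cache$opts
  X <- cache$X
  dG <- dY * (cache$w - cache$q)
  dw <- dY * cache$G
  dq <- dY * (1 - cache$G)
  dX <- matrix(0, nrow(X), ncol(X))
  dparams <- list()
  # nonlinear branch
  dw_pre <- dw * (cache$w_pre > 0)
  dparams$nonlinear <- list(W = crossprod(X, dw_pre), b = colSums(dw_pre))
  dX <- dX + dw_pre %*% t(layer$nonlinear$W)
  # gate
  dgate_pre <- dG * cache$G * (1 - cache$G)
  if (opts$param_free_gate) {
    dX <- dX + dgate_pre
  } else {
    dparams$gate <- list(W = crossprod(X, dgate_pre), b = colSums(dgate_pre))
    dX <- dX + dgate_pre %*% t(layer$gate$W)
  }
  # carry branch
  if (opts$identity_q) {
    dX <- dX + dq
  } else {
    dparams$linear <- list(W = crossprod(X, dq), b = colSums(dq))
    dX <- dX + dq %*% t(layer$linear$W)
  }
  # reorder to match the layer's parameter order for gradient trees
  dparams <- dparams[names(layer)]
  list(dX = dX, dparams = dparams)
}

mfic_stack_fwd <- function(X, params) {
  opts <- params[c("identity_q", "param_free_gate")]
  caches <- vector("list", params$depth)
  for (i in seq_len(params$depth)) {
    fw <- .mfic_layer_fwd(X, params$layers[[i]], opts)
    caches[[i]] <- fw$cache
    X <- fw$out
  }
  list(out = X, caches = caches)
}

mfic_stack_bwd <- function(dY, caches) {
  dlayers <- vector("list", length(caches))
  for (i in rev(seq_along(caches))) {
    bw <- .mfic_layer_bwd(dY, caches[[i]])
    dlayers[[i]] <- bw$dparams
    dY <- bw$dX
  }
  list(dX = dY, dparams = list(layers = dlayers))
}

#' Apply one gated fusion layer
#'
#' Computes `y = g * relu_branch + (1 - g) * linear_branch` elementwise,
#' where `g` is the sigmoid gate. Every output component therefore lies
#' between the two branch values, and saturating the gate recovers either
#' branch exactly.
#'
#' @param F_vec Fused feature vector, or a matrix with one vector per row.
#' @param params An `mfic_params` object.
#' @param layer Which layer of the stack to apply (default 1).
#' @return Same shape as `F_vec`.
#' @export
mfic_layer <- function(F_vec, params, layer = 1L) {
  one <- is.null(dim(F_vec))
  X <- if (one) matrix(F_vec, 1L) else as.matrix(F_vec)
  if (ncol(X) != params$dim)
    stop_config("fused width %d != controller width %d", ncol(X), params$dim)
  opts <- params[c("identity_q", "param_free_gate")]
  out <- .mfic_layer_fwd(X, params$layers[[layer]], opts)$out
  if (one) drop(out) else out
}

#' Apply the full gated fusion stack
#'
#' Depth-fold composition of [mfic_layer()]; width is preserved at every
#' depth.
#'
#' @inheritParams mfic_layer
#' @return Same shape as `F_vec`.
#' @export
mfic_stack <- function(F_vec, params) {
  one <- is.null(dim(F_vec))
  X <- if (one) matrix(F_vec, 1L) else as.matrix(F_vec)
  if (ncol(X) != params$dim)
    stop_config("fused width %d != controller width %d", ncol(X), params$dim)
  out <- mfic_stack_fwd(X, params)$out
  if (one) drop(out) else out
}
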