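# Multi-head graph attention encoder over molecular graphs.
#
# Attention is computed densely: for small molecular graphs a full masked
# n x n logit matrix is cheap, keeps the code close to the defining algebra
# (leaky-rectified additive logits, neighborhood softmax, weighted sum), and
# makes the backward pass a handful of matrix products.

# Dense {0,1} neighborhood mask with self-loops: N(i) always contains i so
# the neighborhood softmax is well defined even for isolated atoms.
graph_adj_mask <- function(graph) {
  n <- graph$num_atoms
  mask <- diag(1, n)
  if (nrow(graph$edges) > 0L) {
    mask[graph$edges] <- 1
    mask[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  mask
}

#' Initialize the parameters of one graph-attention layer
#'
#' Each head carries a Glorot-uniform weight matrix `W` (`in_dim` x
#' `out_dim`) and an attention vector `a` of length `2 * out_dim` whose two
#' halves score the source and destination atom of an edge.
#'
#' @param in_dim,out_dim Input/output width per head.
#' @param num_heads Number of attention heads.
#' @param combine How head outputs are merged: `"concat"` (hidden layers) or
#'   `"average"` (final layer).
#' @param activation Per-head output activation: `"elu"` on hidden layers,
#'   `"identity"` on the final layer.
#' @param negative_slope Slope of the leaky rectifier applied to raw
#'   attention logits before the softmax.
#' @return A `gat_layer_params` list; pass one layer to [gat_layer()] or a
#'   list of layers to [encode_drug()].
#' @export
init_gat_layer <- function(in_dim, out_dim, num_heads = 4L,
                           combine = c("concat", "average"),
                           activation = c("elu", "identity"),
                           negative_slope = 0.2) {
  combine <- match.arg(combine)
  activation <- match.arg(activation)
  stopifnot(is_count(in_dim), is_count(out_dim), is_count(num_heads))
  s <- sqrt(6 / (in_dim + out_dim))
  heads <- lapply(seq_len(num_heads), function(m) {
    list(W = matrix(stats::runif(in_dim * out_dim, -s, s), in_dim, out_dim),
         a = stats::runif(2L * out_dim, -0.1, 0.1))
  })
  structure(list(heads = heads, combine = combine, activation = activation,
                 negative_slope = negative_slope,
                 in_dim = in_dim, out_dim = out_dim),
            class = "gat_layer_params")
}

.gat_act <- function(x, activation) {
  if (activation == "elu") elu(x) else x
}
.gat_act_grad <- function(x, activation) {
  if (activation == "elu") elu_grad(x) else 1
}

# Forward pass of one layer on node matrix X with dense mask; returns output
# and the cache needed by the backward pass.
gat_layer_fwd <- function(X, mask, layer) {
  if (ncol(X) != layer$in_dim)
    stop_config("gat layer expects input width %d, got %d", layer$in_dim, ncol(X))
  n <- nrow(X)
  hd <- layer$out_dim
  heads <- vector("list", length(layer$heads))
  outs <- vector("list", length(layer$heads))
  for (m in seq_along(layer$heads)) {
    p <- layer$heads[[m]]
    Ht <- X %*% p$W                           # n x K'
    f <- drop(Ht %*% p$a[1:hd])               # source score per atom
    g <- drop(Ht %*% p$a[(hd + 1L):(2L * hd)])# destination score per atom
    logits <- outer(f, rep(1, n)) + outer(rep(1, n), g)
    e <- leaky_relu(logits, layer$negative_slope)
    alpha <- softmax_rows(e, mask)
    pre <- alpha %*% Ht
    out <- .gat_act(pre, layer$activation)
    heads[[m]] <- list(Ht = Ht, logits = logits, alpha = alpha, pre = pre)
    outs[[m]] <- out
  }
  out <- if (layer$combine == "concat") do.call(cbind, outs)
         else Reduce(`+`, outs) / length(outs)
  list(out = out, cache = list(X = X, mask = mask, heads = heads, layer = layer))
}

# Backward pass of one layer: d_out -> gradients for X and all head params.
gat_layer_bwd <- function(d_out, cache) {
  layer <- cache$layer
  X <- cache$X
  n <- nrow(X)
  hd <- layer$out_dim
  M <- length(layer$heads)
  dX <- matrix(0, n, ncol(X))
  dheads <- vector("list", M)
  for (m in seq_len(M)) {
    p <- layer$heads[[m]]
    hc <- cache$heads[[m]]
    d_head <- if (layer$combine == "concat")
      d_out[, ((m - 1L) * hd + 1L):(m * hd), drop = FALSE]
    else d_out / M
    d_pre <- d_head * .gat_act_grad(hc$pre, layer$activation)
    d_alpha <- d_pre %*% t(hc$Ht)
    dHt <- t(hc$alpha) %*% d_pre
    # softmax rows (masked): alpha is zero off-mask so the same formula holds
    d_e <- hc$alpha * (d_alpha - rowSums(hc$alpha * d_alpha))
    d_logits <- d_e * leaky_relu_grad(hc$logits, layer$negative_slope)
    d_logits[cache$mask == 0] <- 0
    df <- rowSums(d_logits)
    dg <- colSums(d_logits)
    dHt <- dHt + outer(df, p$a[1:hd]) + outer(dg, p$a[(hd + 1L):(2L * hd)])
    da <- c(drop(t(hc$Ht) %*% df), drop(t(hc$Ht) %*% dg))
    dW <- t(X) %*% dHt
    dX <- dX + dHt %*% t(p$W)
    dheads[[m]] <- list(W = dW, a = da)
  }
  list(dX = dX, dparams = list(heads = dheads))
}

#' Per-edge attention coefficients of a graph-attention layer
#'
#' Computes, for every head, the dense matrix of softmax-normalized attention
#' coefficients over each atom's neighborhood (self-loops included): entry
#' (i, j) is the weight atom i places on neighbor j, rows summing to 1 over
#' the neighborhood.
#'
#' @param embeddings Numeric matrix of per-atom input features/embeddings.
#' @param graph A `molecular_graph`.
#' @param params A `gat_layer_params` object.
#' @return A list with one `num_atoms` x `num_atoms` matrix per head;
#'   entries outside the neighborhood are exactly zero.
#' @export
attention_coefficients <- function(embeddings, graph, params) {
  if (!inherits(graph, "molecular_graph"))
    stop("'graph' must be a molecular_graph", call. = FALSE)
  if (graph$num_atoms < 1L) stop("empty graph", call. = FALSE)
  embeddings <- as.matrix(embeddings)
  fw <- gat_layer_fwd(embeddings, graph_adj_mask(graph), params)
  lapply(fw$cache$heads, `[[`, "alpha")
}

#' Apply one graph-attention layer
#'
#' Each atom's new embedding is the activated, attention-weighted sum of its
#' neighbors' (and its own) linearly transformed embeddings; heads are
#' concatenated or averaged per the layer's `combine` setting.
#'
#' @inheritParams attention_coefficients
#' @return The new per-atom embedding matrix.
#' @export
gat_layer <- function(embeddings, graph, params) {
  if (!inherits(graph, "molecular_graph"))
    stop("'graph' must be a molecular_graph", call. = FALSE)
  if (graph$num_atoms < 1L) stop("empty graph", call. = FALSE)
  embeddings <- as.matrix(embeddings)
  gat_layer_fwd(embeddings, graph_adj_mask(graph), params)$out
}

#' Encode a drug into per-atom embeddings
#'
#' Runs the molecular graph through a stack of graph-attention layers and
#' returns the final layer's per-atom embedding matrix. Pooling to a single
#' graph-level vector is deliberately left to the cross-drug aggregation
#' module, which needs the per-atom resolution.
#'
#' @param graph A `molecular_graph` with node features attached.
#' @param layer_stack A list of `gat_layer_params` (depth >= 1).
#' @return Matrix `num_atoms` x embedding width.
#' @export
#' @examples
#' \donttest{
#' g <- smiles_to_graph("CCO")
#' layers <- with_seed(1, list(
#'   init_gat_layer(atom_feature_info()$width, 8, num_heads = 2),
#'   init_gat_layer(16, 8, num_heads = 2, combine = "average",
#'                  activation = "identity")))
#' dim(encode_drug(g, layers))  # 3 x 8
#' }
encode_drug <- function(graph, layer_stack) {
  if (inherits(layer_stack, "gat_layer_params")) layer_stack <- list(layer_stack)
  if (length(layer_stack) < 1L) stop_config("at least one GAT layer is required")
  X <- graph$node_features
  if (is.null(X)) X <- featurize_atoms(graph)
  mask <- graph_adj_mask(graph)
  for (layer in layer_stack) X <- gat_layer_fwd(X, mask, layer)$out
  X
}

# Full encoder forward with caches (training path).
encode_drug_fwd <- function(graph, layer_stack) {
  X <- graph$node_features
  if (is.null(X)) X <- featurize_atoms(graph)
  mask <- graph_adj_mask(graph)
  caches <- vector("list", length(layer_stack))
  for (i in seq_along(layer_stack)) {
    fw <- gat_layer_fwd(X, mask, layer_stack[[i]])
    caches[[i]] <- fw$cache
    X <- fw$out
  }
  list(out = X, caches = caches)
}

# Backward through the encoder stack; returns per-layer parameter gradients.
encode_drug_bwd <- function(d_out, caches) {
  dlayers <- vector("list", length(caches))
  for (i in rev(seq_along(caches))) {
    bw <- gat_layer_bwd(d_out, caches[[i]])
    dlayers[[i]] <- bw$dparams
    d_out <- bw$dX
  }
  dlayers
}
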