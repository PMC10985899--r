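# Cell-line expression: TPM normalization, gene-panel restriction, and a
# bias-free tanh multilayer perceptron embedding each profile into the same
# width as the drug graph embeddings.

#' Transcripts-per-million normalization
#'
#' Per cell line, counts are first divided by gene length (length-rate),
#' then scaled so every column sums to one million. Corrects for both gene
#' length and sequencing depth.
#'
#' @param counts Numeric matrix, genes x cell lines, non-negative raw
#'   counts; rownames are gene ids, colnames cell ids.
#' @param gene_lengths Positive gene lengths in kilobases, aligned with the
#'   rows of `counts`.
#' @return Matrix of the same shape; each column sums to 1e6 (all-zero
#'   columns stay zero, with a warning).
#' @export
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
#' tpm_normalize(m, c(1, 2))  # 666666.67, 333333.33
tpm_normalize <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must have one entry per gene row", call. = FALSE)
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be positive and finite", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / gene_lengths
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("all-zero expression column(s): %s",
                    paste(colnames(counts)[zero] %||% which(zero), collapse = ", ")))
    totals[zero] <- 1  # keeps the column at exact zero
  }
  sweep(rate, 2L, totals, "/") * 1e6
}

#' Restrict an expression matrix to a gene panel
#'
#' Rows are reordered to follow the panel, not the matrix; panel genes
#' absent from the matrix are dropped with a warning naming them; duplicate
#' panel entries collapse to their first occurrence.
#'
#' @param mat Numeric matrix, genes x cell lines, with gene-id rownames.
#' @param panel Character vector of gene ids.
#' @return The row-subset matrix in panel order.
#' @export
select_genes <- function(mat, panel) {
  mat <- as.matrix(mat)
  if (length(panel) == 0L) stop("gene panel is empty", call. = FALSE)
  panel <- panel[!duplicated(panel)]
  hit <- panel %in% rownames(mat)
  if (!any(hit))
    stop("no panel gene found in the expression matrix", call. = FALSE)
  if (any(!hit))
    warning(sprintf("%d panel gene(s) missing from the expression matrix: %s",
                    sum(!hit), paste(panel[!hit], collapse = ", ")))
  mat[panel[hit], , drop = FALSE]
}

#' Initialize cell-line MLP parameters
#'
#' A stack of bias-free weight matrices, every layer tanh-activated, mapping
#' a gene-panel profile to the drug embedding width.
#'
#' @param in_dim Panel size (input width).
#' @param hidden Integer vector of hidden widths (may be empty).
#' @param out_dim Output width (must equal the drug embedding width).
#' @param bias Add per-layer bias vectors (off by default: the embedding is
#'   a pure weight chain, and a zero profile then maps to zero).
#' @return A `cell_mlp_params` list of weight matrices `W` (and biases `b`
#'   when requested).
#' @export
init_cell_mlp <- function(in_dim, hidden, out_dim, bias = FALSE) {
  dims <- c(in_dim, hidden, out_dim)
  W <- lapply(seq_len(length(dims) - 1L), function(i) {
    s <- sqrt(6 / (dims[i] + dims[i + 1L]))
    matrix(stats::runif(dims[i] * dims[i + 1L], -s, s), dims[i], dims[i + 1L])
  })
  p <- list(W = W)
  if (bias) p$b <- lapply(dims[-1L], function(d) rep(0, d))
  structure(p, class = "cell_mlp_params")
}

#' Embed cell-line profiles with the tanh MLP
#'
#' Applies `v = tanh(... tanh(c W0) ... Wq)`: every layer is a bias-free
#' linear map followed by tanh, so outputs lie strictly inside (-1, 1) and a
#' zero profile maps to the zero vector.
#'
#' @param profile A numeric vector (one profile) or matrix with one profile
#'   per row.
#' @param params A `cell_mlp_params` object.
#' @return Embedding vector, or matrix with one embedding per row.
#' @export
encode_cell <- function(profile, params) {
  one <- is.null(dim(profile))
  X <- if (one) matrix(profile, 1L) else as.matrix(profile)
  if (ncol(X) != nrow(params$W[[1L]]))
    stop_config("profile length %d != MLP input width %d",
                ncol(X), nrow(params$W[[1L]]))
  out <- cell_mlp_fwd(X, params)$out
  if (one) drop(out) else out
}

cell_mlp_fwd <- function(X, params) {
  acts <- vector("list", length(params$W) + 1L)
  acts[[1L]] <- X
  for (i in seq_along(params$W)) {
    pre <- acts[[i]] %*% params$W[[i]]
    if (!is.null(params$b)) pre <- pre + rep(params$b[[i]], each = nrow(X))
    acts[[i + 1L]] <- tanh(pre)
  }
  list(out = acts[[length(acts)]], cache = list(acts = acts, params = params))
}

cell_mlp_bwd <- function(d_out, cache) {
  W <- cache$params$W
  has_b <- !is.null(cache$params$b)
  acts <- cache$acts
  dW <- vector("list", length(W))
  db <- if (has_b) vector("list", length(W)) else NULL
  for (i in rev(seq_along(W))) {
    d_pre <- d_out * (1 - acts[[i + 1L]]^2)   # tanh'
    dW[[i]] <- crossprod(acts[[i]], d_pre)
    if (has_b) db[[i]] <- colSums(d_pre)
    d_out <- d_pre %*% t(W[[i]])
  }
  dp <- list(W = dW)
  if (has_b) dp$b <- db
  list(dX = d_out, dparams = dp)
}
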