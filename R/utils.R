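# Internal numerical and bookkeeping helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the generator seeded at `seed`, then restores the
#' caller's RNG state, so seeded package calls never perturb user
#' simulations. A `NULL` seed evaluates `expr` untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Row-wise softmax of a matrix with an optional {0,1} mask: masked-out entries
# receive zero probability and rows are normalized over the surviving entries.
softmax_rows <- function(x, mask = NULL) {
  if (!is.null(mask)) x[mask == 0] <- -Inf
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  if (!is.null(mask)) e[mask == 0] <- 0
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Layer normalization over the feature axis, no learnable affine.
# Returns the normalized vector; cache carries what backward needs.
layer_norm <- function(u, ln_eps = 1e-5) {
  mu <- mean(u)
  v <- mean((u - mu)^2)
  s <- sqrt(v + ln_eps)
  uhat <- (u - mu) / s
  list(out = uhat, uhat = uhat, s = s)
}

layer_norm_grad <- function(dout, cache) {
  n <- length(dout)
  uhat <- cache$uhat
  (dout - mean(dout) - uhat * mean(dout * uhat)) / cache$s
}

# --- flat parameter vector <-> nested list of matrices/vectors ---------------
# The optimizer works on one flat numeric vector; modules see nested lists.

par_flatten <- function(params) {
  unlist(params, use.names = FALSE)
}

par_skeleton <- function(params) params

par_unflatten <- function(vec, skeleton) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) return(lapply(node, rebuild))
    n <- length(node)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(node)) dim(out) <- dim(node)
    out
  }
  out <- rebuild(skeleton)
  stopifnot(pos == length(vec))
  out
}

# Elementwise combination of two parameter trees with identical shape.
par_zip <- function(a, b, f) {
  if (is.list(a)) return(mapply(par_zip, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}

par_map <- function(a, f) {
  if (is.list(a)) return(lapply(a, par_map, f = f))
  f(a)
}

# Zero tree with the same shape as `params` (gradient accumulator).
par_zero <- function(params) par_map(params, function(x) x * 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
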