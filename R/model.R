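# Model assembly: configuration, parameter initialization, the full batch
# forward/backward pass, and the user-facing fitted-model object.
#
# Trainable parameters live in a pure-numeric nested list (`params`) so the
# optimizer can treat them as one flat vector; architectural metadata
# (widths, head counts, activation choices) lives in a parallel `meta` list.
# Small "view" helpers reassemble the classed objects the module-level
# functions expect.

#' Model configuration
#'
#' All tunable hyperparameters of the synergy model in one validated list.
#' Defaults follow the published setup where stated (graph-attention width
#' 64, batch size 128, learning rate 1e-4, dropout 0.1) and conventional
#' choices elsewhere.
#'
#' @param gat_layers Number of graph-attention layers (depth).
#' @param gat_heads Attention heads per hidden layer.
#' @param gat_hidden Hidden width per head.
#' @param embedding_dim Final per-atom (and graph-level) embedding width;
#'   hidden-layer heads are concatenated, final-layer heads averaged.
#' @param negative_slope Leaky-rectifier slope for attention logits.
#' @param aagam_tied Share the cross-attention projections between the
#'   A-against-B and B-against-A directions (default) or learn two sets.
#' @param cell_hidden Hidden widths of the cell-line MLP (vector allowed).
#' @param cell_bias Add bias vectors to the cell MLP (off by default; the
#'   published formulation is a pure weight chain).
#' @param cell_transform `"auto"` (log2(x+1) when the matrix is
#'   non-negative, identity otherwise), `"log2"`, or `"none"`.
#' @param mfic_depth Depth of the gated fusion stack.
#' @param mfic_gate_bias Initial gate bias (negative favors the carry path
#'   early in training).
#' @param mfic_identity_q Use an identity carry branch instead of a
#'   learnable affine.
#' @param mfic_param_free_gate Gate as `sigmoid(F)` without parameters
#'   (ablation mode).
#' @param head_hidden Hidden width of the classification head.
#' @param dropout Dropout rate in (0, 1), applied to the fused vector and
#'   the head hidden layer during training.
#' @param kl_alpha Weight of the symmetric KL consistency term.
#' @param kl_alpha_learnable Make the KL weight a learnable non-negative
#'   scalar (softplus-parameterized, initialized at `kl_alpha`).
#' @param eps Numeric floor for logarithms in the loss.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param learning_rate Optimizer step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs (validation AUROC);
#'   `Inf` disables early stopping.
#' @param preset `"default"`, or `"fast"` which raises the learning rate to
#'   1e-3 (the alternative published setting).
#' @return A `synergy_config` list.
#' @export
synergy_config <- function(gat_layers = 2L, gat_heads = 4L, gat_hidden = 64L,
                           embedding_dim = 64L, negative_slope = 0.2,
                           aagam_tied = TRUE,
                           cell_hidden = 256L, cell_bias = FALSE,
                           cell_transform = c("auto", "log2", "none"),
                           mfic_depth = 2L, mfic_gate_bias = -1,
                           mfic_identity_q = FALSE,
                           mfic_param_free_gate = FALSE,
                           head_hidden = 128L, dropout = 0.1,
                           kl_alpha = 1, kl_alpha_learnable = FALSE,
                           eps = 1e-12,
                           optimizer = c("adam", "sgd"),
                           learning_rate = 1e-4, batch_size = 128L,
                           max_epochs = 50L, patience = 5L,
                           preset = c("default", "fast")) {
  preset <- match.arg(preset)
  if (preset == "fast" && missing(learning_rate)) learning_rate <- 1e-3
  cfg <- list(
    gat_layers = as.integer(gat_layers), gat_heads = as.integer(gat_heads),
    gat_hidden = as.integer(gat_hidden),
    embedding_dim = as.integer(embedding_dim),
    negative_slope = negative_slope, aagam_tied = isTRUE(aagam_tied),
    cell_hidden = as.integer(cell_hidden), cell_bias = isTRUE(cell_bias),
    cell_transform = match.arg(cell_transform),
    mfic_depth = as.integer(mfic_depth), mfic_gate_bias = mfic_gate_bias,
    mfic_identity_q = isTRUE(mfic_identity_q),
    mfic_param_free_gate = isTRUE(mfic_param_free_gate),
    head_hidden = as.integer(head_hidden), dropout = dropout,
    kl_alpha = kl_alpha, kl_alpha_learnable = isTRUE(kl_alpha_learnable),
    eps = eps, optimizer = match.arg(optimizer),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = patience,
    preset = preset)
  stopifnot(cfg$gat_layers >= 1L, cfg$gat_heads >= 1L,
            cfg$gat_hidden >= 1L, cfg$embedding_dim >= 1L,
            cfg$mfic_depth >= 1L, cfg$head_hidden >= 1L)
  if (!(cfg$dropout >= 0 && cfg$dropout < 1))
    stop_config("dropout must be in [0, 1)")
  if (cfg$kl_alpha < 0) stop_config("kl_alpha must be >= 0")
  if (cfg$eps <= 0) stop_config("eps must be > 0")
  if (cfg$learning_rate <= 0) stop_config("learning_rate must be > 0")
  if (cfg$batch_size < 1L) stop_config("batch_size must be >= 1")
  structure(cfg, class = "synergy_config")
}

# Split a classed module init into numeric weights + static metadata.
.split_gat_layer <- function(layer) {
  list(weights = list(heads = layer$heads),
       meta = layer[c("combine", "activation", "negative_slope",
                      "in_dim", "out_dim")])
}

.gat_layer_view <- function(params_layer, meta_layer) {
  structure(c(params_layer, meta_layer), class = "gat_layer_params")
}

.mfic_view <- function(params_mfic, meta_mfic) {
  structure(c(list(layers = params_mfic$layers), meta_mfic),
            class = "mfic_params")
}

# Architecture of the GAT stack for a given config: list of (in, out,
# heads, combine, activation).
.gat_plan <- function(config) {
  d0 <- atom_feature_info()$width
  L <- config$gat_layers
  plan <- vector("list", L)
  for (i in seq_len(L)) {
    in_dim <- if (i == 1L) d0 else config$gat_hidden * config$gat_heads
    if (i == L) {
      plan[[i]] <- list(in_dim = in_dim, out_dim = config$embedding_dim,
                        combine = "average", activation = "identity")
    } else {
      plan[[i]] <- list(in_dim = in_dim, out_dim = config$gat_hidden,
                        combine = "concat", activation = "elu")
    }
  }
  plan
}

# Initialize all trainable parameters (pure numeric tree) plus metadata.
.init_model_params <- function(config, n_panel_genes) {
  plan <- .gat_plan(config)
  gat_w <- list(); gat_m <- list()
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    layer <- init_gat_layer(p$in_dim, p$out_dim, config$gat_heads,
                            combine = p$combine, activation = p$activation,
                            negative_slope = config$negative_slope)
    sp <- .split_gat_layer(layer)
    gat_w[[i]] <- sp$weights
    gat_m[[i]] <- sp$meta
  }
  K <- config$embedding_dim
  aagam <- if (config$aagam_tied) unclass(init_aagam_params(K))
           else list(AB = unclass(init_aagam_params(K)),
                     BA = unclass(init_aagam_params(K)))
  cell <- unclass(init_cell_mlp(n_panel_genes, config$cell_hidden, K,
                                bias = config$cell_bias))
  fused_dim <- 3L * K
  mfic_full <- init_mfic_params(fused_dim, config$mfic_depth,
                                gate_bias_init = config$mfic_gate_bias,
                                identity_q = config$mfic_identity_q,
                                param_free_gate = config$mfic_param_free_gate)
  mfic_w <- list(layers = mfic_full$layers)
  mfic_m <- mfic_full[c("dim", "depth", "identity_q", "param_free_gate")]
  head <- unclass(init_head_params(fused_dim, config$head_hidden))
  params <- list(gat = gat_w, aagam = aagam, cell = cell, mfic = mfic_w,
                 head = head)
  if (config$kl_alpha_learnable) {
    # softplus^-1 so the learnable weight starts at kl_alpha
    params$alpha_raw <- log(expm1(max(config$kl_alpha, 1e-6)))
  }
  list(params = params, meta = list(gat = gat_m, mfic = mfic_m))
}

.model_alpha <- function(model) {
  if (!is.null(model$params$alpha_raw)) log1p(exp(model$params$alpha_raw))
  else model$config$kl_alpha
}

# Apply the configured expression transform; returns cells x genes.
.prepare_cell_matrix <- function(expression, panel, transform) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)))
    stop("expression matrix needs gene-id rownames", call. = FALSE)
  if (is.null(colnames(expression)))
    stop("expression matrix needs cell-id colnames", call. = FALSE)
  if (!is.null(panel)) expression <- select_genes(expression, panel)
  use_log <- switch(transform,
    log2 = TRUE, none = FALSE,
    auto = min(expression) >= 0)
  if (use_log) {
    if (min(expression) < 0)
      stop("log2 transform requires a non-negative expression matrix",
           call. = FALSE)
    expression <- log2(expression + 1)
  }
  structure(t(expression), transform_applied = use_log)
}

#' Initialize an untrained synergy model
#'
#' Parses the drug library, prepares the cell-line matrix and draws fresh
#' parameters. [synergy_fit()] calls this and then trains; an untrained
#' model is also directly usable for forward-pass analyses and tests.
#'
#' @param drugs A data.frame with columns `drug_id`, `smiles`.
#' @param expression Numeric matrix, genes x cell lines (gene-id rownames,
#'   cell-id colnames). Expected TPM-scale or otherwise normalized; see
#'   `cell_transform` in [synergy_config()].
#' @param panel Optional character vector of gene ids restricting and
#'   ordering the expression rows (see [select_genes()]).
#' @param config A [synergy_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `synergy_model` (untrained).
#' @export
synergy_init <- function(drugs, expression, panel = NULL,
                         config = synergy_config(), seed = 1L) {
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  if (anyDuplicated(drugs$drug_id))
    stop("duplicate drug_id in drug table", call. = FALSE)
  graphs <- lapply(drugs$smiles, smiles_to_graph)
  names(graphs) <- drugs$drug_id
  cell_mat <- .prepare_cell_matrix(expression, panel, config$cell_transform)
  init <- with_seed(seed, .init_model_params(config, ncol(cell_mat)))
  structure(list(
    params = init$params, meta = init$meta, config = config,
    drug_ids = drugs$drug_id, smiles = drugs$smiles, graphs = graphs,
    cell_mat = cell_mat, cell_ids = rownames(cell_mat),
    panel = if (is.null(panel)) colnames(cell_mat) else panel,
    seed = seed, trained = FALSE, history = NULL),
    class = "synergy_model")
}

# Map triplet ids to indices against the model's libraries.
.resolve_triplets <- function(model, triplets) {
  need <- c("drug_a", "drug_b", "cell_line")
  miss <- setdiff(need, names(triplets))
  if (length(miss))
    stop(sprintf("triplets lack column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  ai <- match(triplets$drug_a, model$drug_ids)
  bi <- match(triplets$drug_b, model$drug_ids)
  ci <- match(triplets$cell_line, model$cell_ids)
  bad <- which(is.na(ai) | is.na(bi) | is.na(ci))
  if (length(bad))
    stop(sprintf("unknown drug/cell id in triplet row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  list(a = ai, b = bi, cell = ci,
       label = if ("label" %in% names(triplets)) triplets$label else NULL)
}

# Inverted-dropout masks (already divided by the keep rate).
.make_masks <- function(B, fused_dim, head_hidden, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  list(F = matrix(stats::rbinom(B * fused_dim, 1L, keep), B) / keep,
       H = matrix(stats::rbinom(B * head_hidden, 1L, keep), B) / keep)
}

# Shared (dropout-free) part of the forward pass: drug encoders, cross-drug
# aggregation, cell MLP, concatenation into the fused matrix F0.
.forward_shared <- function(model, idx, keep_cache = FALSE) {
  cfg <- model$config
  K <- cfg$embedding_dim
  B <- length(idx$a)
  gat_views <- lapply(seq_along(model$params$gat), function(i)
    .gat_layer_view(model$params$gat[[i]], model$meta$gat[[i]]))

  ud <- sort(unique(c(idx$a, idx$b)))
  enc <- vector("list", max(ud))
  for (d in ud) enc[[d]] <- encode_drug_fwd(model$graphs[[d]], gat_views)

  uc <- sort(unique(idx$cell))
  cell_fw <- cell_mlp_fwd(model$cell_mat[uc, , drop = FALSE],
                          model$params$cell)
  cell_row <- match(idx$cell, uc)

  pA <- if (cfg$aagam_tied) model$params$aagam else model$params$aagam$AB
  pB <- if (cfg$aagam_tied) model$params$aagam else model$params$aagam$BA
  Gx <- matrix(0, B, K); Gy <- matrix(0, B, K)
  pair_caches <- if (keep_cache) vector("list", B) else NULL
  scores <- vector("list", B)
  for (s in seq_len(B)) {
    EA <- enc[[idx$a[s]]]$out
    EB <- enc[[idx$b[s]]]$out
    fa <- aagam_dir_fwd(EA, EB, pA)
    fb <- aagam_dir_fwd(EB, EA, pB)
    Gx[s, ] <- fa$G; Gy[s, ] <- fb$G
    scores[[s]] <- list(A = fa$scores, B = fb$scores)
    if (keep_cache) pair_caches[[s]] <- list(a = fa$cache, b = fb$cache)
  }

  F0 <- cbind(Gx, Gy, cell_fw$out[cell_row, , drop = FALSE])
  out <- list(F0 = F0, scores = scores)
  if (keep_cache)
    out$cache <- list(enc = enc, ud = ud, uc = uc, cell_fw = cell_fw,
                      cell_row = cell_row, pair = pair_caches,
                      idx = idx, B = B, K = K)
  out
}

# Dropout-bearing tail: fusion controller + classification head.
.forward_head <- function(model, F0, masks = NULL, keep_cache = FALSE) {
  Fd <- if (!is.null(masks)) F0 * masks$F else F0
  mfic_view <- .mfic_view(model$params$mfic, model$meta$mfic)
  mf <- mfic_stack_fwd(Fd, mfic_view)
  hd <- head_fwd(mf$out, structure(model$params$head, class = "head_params"),
                 drop_mask = if (!is.null(masks)) masks$H else NULL)
  out <- list(P = hd$P, Z = hd$Z)
  if (keep_cache)
    out$cache <- list(mfic = mf$caches, head = hd$cache, masks = masks)
  out
}

# Full forward pass over a set of resolved triplets.
.model_forward <- function(model, idx, masks = NULL, keep_cache = FALSE) {
  sh <- .forward_shared(model, idx, keep_cache = keep_cache)
  tl <- .forward_head(model, sh$F0, masks = masks, keep_cache = keep_cache)
  out <- list(P = tl$P, Z = tl$Z, scores = sh$scores)
  if (keep_cache) out$cache <- list(shared = sh$cache, tail = tl$cache)
  out
}

# Backward through the dropout-bearing tail: dZ -> head/fusion gradients
# plus the gradient reaching the fused matrix F0.
.backward_head <- function(model, dZ, tail_cache) {
  hb <- head_bwd(dZ, tail_cache$head)
  mb <- mfic_stack_bwd(hb$dX, tail_cache$mfic)
  dF <- mb$dX
  if (!is.null(tail_cache$masks)) dF <- dF * tail_cache$masks$F
  list(dF0 = dF, head = hb$dparams, mfic = mb$dparams)
}

# Backward through the shared part given the gradient on F0.
.backward_shared <- function(model, dF0, cache) {
  cfg <- model$config
  K <- cache$K
  idx <- cache$idx
  dGx <- dF0[, 1:K, drop = FALSE]
  dGy <- dF0[, (K + 1L):(2L * K), drop = FALSE]
  dV <- dF0[, (2L * K + 1L):(3L * K), drop = FALSE]

  # cell branch: accumulate per unique cell then one MLP backward
  dVu <- matrix(0, length(cache$uc), K)
  for (s in seq_len(cache$B))
    dVu[cache$cell_row[s], ] <- dVu[cache$cell_row[s], ] + dV[s, ]
  cell <- cell_mlp_bwd(dVu, cache$cell_fw$cache)$dparams

  # pair branch: per-sample aggregation backward, embedding grads per drug
  dE <- vector("list", max(cache$ud))
  for (d in cache$ud) dE[[d]] <- 0 * cache$enc[[d]]$out
  d_aagam_A <- NULL; d_aagam_B <- NULL
  for (s in seq_len(cache$B)) {
    ba <- aagam_dir_bwd(dGx[s, ], cache$pair[[s]]$a)
    bb <- aagam_dir_bwd(dGy[s, ], cache$pair[[s]]$b)
    dE[[idx$a[s]]] <- dE[[idx$a[s]]] + ba$dE_self + bb$dE_other
    dE[[idx$b[s]]] <- dE[[idx$b[s]]] + ba$dE_other + bb$dE_self
    d_aagam_A <- if (is.null(d_aagam_A)) ba$dparams
                 else par_zip(d_aagam_A, ba$dparams, `+`)
    d_aagam_B <- if (is.null(d_aagam_B)) bb$dparams
                 else par_zip(d_aagam_B, bb$dparams, `+`)
  }
  aagam <- if (cfg$aagam_tied) par_zip(d_aagam_A, d_aagam_B, `+`)
           else list(AB = d_aagam_A, BA = d_aagam_B)

  # encoder backward, summed over the drugs in the batch
  d_gat <- NULL
  for (d in cache$ud) {
    dl <- encode_drug_bwd(dE[[d]], cache$enc[[d]]$caches)
    d_gat <- if (is.null(d_gat)) dl else par_zip(d_gat, dl, `+`)
  }
  list(gat = d_gat, aagam = aagam, cell = cell)
}

# Single-pass backward (used by gradient checks): dZ -> full gradient tree.
.model_backward <- function(model, dZ, cache) {
  tb <- .backward_head(model, dZ, cache$tail)
  sb <- .backward_shared(model, tb$dF0, cache$shared)
  grads <- par_zero(model$params)
  grads$gat <- sb$gat; grads$aagam <- sb$aagam; grads$cell <- sb$cell
  grads$mfic <- tb$mfic; grads$head <- tb$head
  grads
}

# One dual-pass training step: shared forward once, two dropout branches,
# combined loss gradient, shared backward once. Returns loss + gradients.
.train_step <- function(model, idx, rate, alpha) {
  cfg <- model$config
  B <- length(idx$a)
  sh <- .forward_shared(model, idx, keep_cache = TRUE)
  m1 <- .make_masks(B, 3L * cfg$embedding_dim, cfg$head_hidden, rate)
  m2 <- .make_masks(B, 3L * cfg$embedding_dim, cfg$head_hidden, rate)
  t1 <- .forward_head(model, sh$F0, masks = m1, keep_cache = TRUE)
  t2 <- .forward_head(model, sh$F0, masks = m2, keep_cache = TRUE)
  dl <- dual_loss_grads(t1$P, t2$P, idx$label, alpha, cfg$eps)
  b1 <- .backward_head(model, dl$dZ1, t1$cache)
  b2 <- .backward_head(model, dl$dZ2, t2$cache)
  sb <- .backward_shared(model, b1$dF0 + b2$dF0, sh$cache)
  grads <- par_zero(model$params)
  grads$gat <- sb$gat; grads$aagam <- sb$aagam; grads$cell <- sb$cell
  grads$mfic <- par_zip(b1$mfic, b2$mfic, `+`)
  grads$head <- par_zip(b1$head, b2$head, `+`)
  if (!is.null(model$params$alpha_raw))
    grads$alpha_raw <- dl$dalpha * sigmoid(model$params$alpha_raw)
  list(loss = dl$loss, ce = dl$ce, kl = dl$kl, grads = grads)
}

#' Dual-pass training loss for a set of triplets
#'
#' Forwards every sample twice through the model with independent dropout
#' draws and returns the mean of the dual-pass objective: half the sum of
#' both cross-entropies plus `alpha` times the symmetric KL divergence
#' between the two predictive distributions. With dropout 0 the two passes
#' coincide and the loss reduces exactly to the cross-entropy.
#'
#' @param model A `synergy_model`.
#' @param triplets Data.frame with `drug_a`, `drug_b`, `cell_line`, `label`.
#' @param dropout Dropout rate; defaults to the model configuration.
#' @param kl_alpha KL weight; defaults to the model's current value.
#' @param seed Optional seed for the dropout draws.
#' @return The scalar loss, with attributes `ce` and `kl` (its components).
#' @export
dual_pass_loss <- function(model, triplets, dropout = NULL, kl_alpha = NULL,
                           seed = NULL) {
  stopifnot(inherits(model, "synergy_model"))
  idx <- .resolve_triplets(model, triplets)
  if (is.null(idx$label)) stop("triplets need a 'label' column", call. = FALSE)
  rate <- dropout %||% model$config$dropout
  alpha <- kl_alpha %||% .model_alpha(model)
  cfg <- model$config
  B <- length(idx$a)
  with_seed(seed, {
    m1 <- .make_masks(B, 3L * cfg$embedding_dim, cfg$head_hidden, rate)
    m2 <- .make_masks(B, 3L * cfg$embedding_dim, cfg$head_hidden, rate)
    f1 <- .model_forward(model, idx, masks = m1)
    f2 <- .model_forward(model, idx, masks = m2)
    dl <- dual_loss_grads(f1$P, f2$P, idx$label, alpha, cfg$eps)
    structure(dl$loss, ce = dl$ce, kl = dl$kl)
  })
}

#' Predict synergy for drug-pair/cell-line triplets
#'
#' @param object A fitted (or initialized) `synergy_model`.
#' @param newdata Data.frame with columns `drug_a`, `drug_b`, `cell_line`;
#'   ids must come from the model's drug and cell libraries.
#' @param type `"prob"` for the synergy-class probability, `"class"` for
#'   the thresholded 0/1 label, `"logits"` for the raw two-column logit
#'   matrix.
#' @param ... Unused.
#' @return Numeric vector, integer vector, or matrix per `type`.
#' @export
predict.synergy_model <- function(object, newdata,
                                  type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  idx <- .resolve_triplets(object, newdata)
  fw <- .model_forward(object, idx)
  switch(type,
    prob = fw$P[, 2L],
    class = as.integer(fw$P[, 2L] > 0.5),
    logits = fw$Z)
}

#' Per-atom attention report for drug pairs
#'
#' Exports the cross-drug attention scores that the aggregation module
#' assigns to every atom: for each triplet and each drug of the pair, one
#' row per atom with its element symbol and importance score. Scores sum to
#' 1 within each (triplet, drug) group and are the quantity visualized as
#' atom coloring in substructure-interpretation figures.
#'
#' @param model A `synergy_model`.
#' @param triplets Data.frame with `drug_a`, `drug_b`, `cell_line`.
#' @return A data.frame with columns `triplet_id`, `drug_slot` ("A"/"B"),
#'   `drug_id`, `atom_index`, `symbol`, `score`.
#' @export
attention_report <- function(model, triplets) {
  stopifnot(inherits(model, "synergy_model"))
  idx <- .resolve_triplets(model, triplets)
  fw <- .model_forward(model, idx)
  rows <- lapply(seq_along(idx$a), function(s) {
    ga <- model$graphs[[idx$a[s]]]
    gb <- model$graphs[[idx$b[s]]]
    rbind(
      data.frame(triplet_id = s, drug_slot = "A",
                 drug_id = model$drug_ids[idx$a[s]],
                 atom_index = seq_len(ga$num_atoms),
                 symbol = ga$atom_symbols,
                 score = fw$scores[[s]]$A, stringsAsFactors = FALSE),
      data.frame(triplet_id = s, drug_slot = "B",
                 drug_id = model$drug_ids[idx$b[s]],
                 atom_index = seq_len(gb$num_atoms),
                 symbol = gb$atom_symbols,
                 score = fw$scores[[s]]$B, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' @export
print.synergy_model <- function(x, ...) {
  cfg <- x$config
  cat("Drug-combination synergy model (graph attention + gated fusion)\n")
  cat(sprintf("  drugs: %d   cell lines: %d   gene panel: %d\n",
              length(x$drug_ids), length(x$cell_ids), ncol(x$cell_mat)))
  cat(sprintf("  encoder: %d GAT layer(s), %d head(s), width %d -> embedding %d\n",
              cfg$gat_layers, cfg$gat_heads, cfg$gat_hidden, cfg$embedding_dim))
  cat(sprintf("  fusion: depth-%d gated controller on width %d; head hidden %d\n",
              cfg$mfic_depth, 3L * cfg$embedding_dim, cfg$head_hidden))
  cat(sprintf("  parameters: %s   trained: %s\n",
              format(length(par_flatten(x$params)), big.mark = ","),
              if (x$trained) sprintf("yes (%d epochs)", nrow(x$history)) else "no"))
  invisible(x)
}

#' @export
summary.synergy_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last rows):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  if (!is.null(object$eval)) {
    cat("\nHeld-out evaluation:\n")
    print(unlist(object$eval[c("auroc", "aupr", "acc", "bacc", "prec",
                               "tpr", "tnr", "kappa")]))
  }
  invisible(object)
}

#' @export
coef.synergy_model <- function(object, ...) object$params

#' @export
plot.synergy_model <- function(x, ...) {
  if (is.null(x$history)) {
    warning("model has no training history")
    return(invisible(x))
  }
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss", ...)
  if (!all(is.na(h$val_auroc))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_auroc, type = "b", col = "firebrick",
                   pch = 1, axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "firebrick")
    graphics::mtext("validation AUROC", side = 4, line = 2, col = "firebrick")
  }
  invisible(x)
}

#' Simulate labels from the fitted class probabilities
#'
#' @param object A `synergy_model`.
#' @param nsim Number of label sets to draw.
#' @param seed Optional RNG seed.
#' @param newdata Triplets to simulate for (required).
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of Bernoulli draws from the
#'   predicted synergy probabilities.
#' @export
simulate.synergy_model <- function(object, nsim = 1, seed = NULL,
                                   newdata = NULL, ...) {
  if (is.null(newdata)) stop("simulate needs 'newdata' triplets", call. = FALSE)
  p <- predict(object, newdata)
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Deviance residuals of a synergy model
#'
#' @param object A `synergy_model`.
#' @param newdata Triplets with a `label` column (required).
#' @param ... Unused.
#' @return Signed square-root deviance contributions, as in binomial GLMs.
#' @export
residuals.synergy_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata) || is.null(newdata$label))
    stop("residuals need 'newdata' triplets with a 'label' column", call. = FALSE)
  p <- predict(object, newdata)
  y <- newdata$label
  dev <- 2 * cross_entropy(p, y, object$config$eps)
  sign(y - p) * sqrt(dev)
}
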