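# Training: minibatch optimization of the dual-pass objective with Adam (or
# plain SGD), optional early stopping on validation AUROC, and the fivefold
# cross-validation protocol.

.opt_init <- function(n, optimizer) {
  if (optimizer == "adam") list(m = numeric(n), v = numeric(n), t = 0L)
  else list()
}

.opt_step <- function(flat, grad, state, config) {
  lr <- config$learning_rate
  if (config$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    state$m <- b1 * state$m + (1 - b1) * grad
    state$v <- b2 * state$v + (1 - b2) * grad^2
    mhat <- state$m / (1 - b1^state$t)
    vhat <- state$v / (1 - b2^state$t)
    flat <- flat - lr * mhat / (sqrt(vhat) + eps)
  } else {
    flat <- flat - lr * grad
  }
  list(flat = flat, state = state)
}

# Resolve labels: route loewe_score through the threshold rule when no
# label column is present, dropping dead-zone rows.
.ensure_labels <- function(triplets) {
  if (!"label" %in% names(triplets)) {
    if (!"loewe_score" %in% names(triplets))
      stop("triplets need a 'label' or 'loewe_score' column", call. = FALSE)
    lab <- label_by_loewe(triplets$loewe_score)
    drop <- is.na(lab)
    if (any(drop))
      message(sprintf("discarding %d triplet(s) in the Loewe dead zone [0, 10]",
                      sum(drop)))
    triplets <- triplets[!drop, , drop = FALSE]
    triplets$label <- lab[!drop]
  }
  if (any(!triplets$label %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  if (any(triplets$drug_a == triplets$drug_b))
    stop("self-pairs (drug_a == drug_b) are not valid triplets", call. = FALSE)
  triplets
}

#' Fit the drug-combination synergy model
#'
#' End-to-end training: drugs are parsed to molecular graphs and encoded
#' with the graph-attention stack, pairs are pooled by cross-drug attention,
#' cell lines embedded by the tanh MLP, and the fused representation is
#' classified through the gated controller and softmax head. Optimization
#' minimizes the dual-pass objective (two independent dropout passes per
#' sample; cross-entropy plus symmetric KL consistency) with Adam by
#' default. When validation triplets are supplied, training keeps the
#' parameters of the best validation-AUROC epoch and stops early after
#' `patience` epochs without improvement.
#'
#' @param triplets Data.frame with `drug_a`, `drug_b`, `cell_line` and
#'   either `label` (0/1) or `loewe_score` (thresholded via
#'   [label_by_loewe()], dead-zone rows dropped).
#' @param drugs Data.frame with `drug_id`, `smiles`.
#' @param expression Genes x cell-lines matrix (see [synergy_init()]).
#' @param panel Optional gene panel (character vector of gene ids).
#' @param config A [synergy_config()].
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param validation Optional triplet data.frame monitored each epoch.
#' @param verbose Print per-epoch progress.
#' @return A trained `synergy_model`; `$history` holds per-epoch loss and
#'   validation AUROC, `$eval` the final validation report (if validation
#'   was supplied).
#' @export
synergy_fit <- function(triplets, drugs, expression, panel = NULL,
                        config = synergy_config(), seed = 1L,
                        validation = NULL, verbose = FALSE) {
  triplets <- .ensure_labels(triplets)
  if (!is.null(validation)) validation <- .ensure_labels(validation)
  model <- synergy_init(drugs, expression, panel = panel, config = config,
                        seed = seed)
  idx_all <- .resolve_triplets(model, triplets)
  val_idx <- if (!is.null(validation)) .resolve_triplets(model, validation)
  n <- length(idx_all$a)
  flat <- par_flatten(model$params)
  skel <- model$params
  state <- .opt_init(length(flat), config$optimizer)
  best <- list(auroc = -Inf, flat = flat, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auroc = numeric(0))

  with_seed(seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- perm[start:min(start + config$batch_size - 1L, n)]
        idx <- list(a = idx_all$a[rows], b = idx_all$b[rows],
                    cell = idx_all$cell[rows], label = idx_all$label[rows])
        st <- .train_step(model, idx, config$dropout, .model_alpha(model))
        if (!is.finite(st$loss))
          stop(sprintf(
            "training diverged (non-finite loss) at epoch %d; try a lower learning rate",
            epoch), call. = FALSE)
        losses <- c(losses, st$loss)
        up <- .opt_step(flat, par_flatten(st$grads), state, config)
        flat <- up$flat; state <- up$state
        model$params <- par_unflatten(flat, skel)
      }
      val_auroc <- NA_real_
      if (!is.null(val_idx)) {
        vp <- .model_forward(model, val_idx)$P[, 2L]
        val_auroc <- .auroc(vp, val_idx$label)
        if (val_auroc > best$auroc + 1e-6) {
          best <- list(auroc = val_auroc, flat = flat, epoch = epoch)
          wait <- 0L
        } else wait <- wait + 1L
      }
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), val_auroc)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  val AUROC %s\n", epoch,
                    mean(losses),
                    if (is.na(val_auroc)) "-" else sprintf("%.4f", val_auroc)))
      if (!is.null(val_idx) && wait > config$patience) break
    }
  })

  if (!is.null(val_idx) && is.finite(best$auroc)) {
    model$params <- par_unflatten(best$flat, skel)
    model$best_epoch <- best$epoch
  }
  model$trained <- TRUE
  model$history <- history
  if (!is.null(validation)) {
    vp <- predict(model, validation)
    model$eval <- compute_metrics(vp, validation$label)
  }
  model
}

#' Fivefold cross-validation of the synergy model
#'
#' Splits the data 90/10 into training and test portions (stratified), then
#' runs fivefold cross-validation on the training portion: each fold in
#' turn serves as the validation set (driving early stopping) while the
#' remaining folds train the model, mirroring the published protocol.
#'
#' @inheritParams synergy_fit
#' @param n_folds Number of folds (default 5).
#' @return A `synergy_cv` object: per-fold `eval_report`s, their
#'   mean and standard deviation, the held-out test report of the last
#'   fold's model, and the split itself.
#' @export
synergy_cv <- function(triplets, drugs, expression, panel = NULL,
                       config = synergy_config(), seed = 1L, n_folds = 5L,
                       verbose = FALSE) {
  triplets <- .ensure_labels(triplets)
  sp <- split_dataset(triplets, seed = seed, n_folds = n_folds)
  reports <- vector("list", n_folds)
  model <- NULL
  for (f in seq_len(n_folds)) {
    va <- sp$train[sp$folds[[f]], , drop = FALSE]
    tr <- sp$train[-sp$folds[[f]], , drop = FALSE]
    model <- synergy_fit(tr, drugs, expression, panel = panel,
                         config = config, seed = seed + f,
                         validation = va, verbose = verbose)
    reports[[f]] <- model$eval
  }
  keys <- c("auroc", "aupr", "acc", "bacc", "prec", "tpr", "tnr", "kappa")
  tab <- sapply(reports, function(r) unlist(r[keys]))
  test_report <- compute_metrics(predict(model, sp$test), sp$test$label)
  structure(list(folds = reports,
                 mean = rowMeans(tab), sd = apply(tab, 1L, stats::sd),
                 test = test_report, split = sp, last_model = model),
            class = "synergy_cv")
}

#' @export
print.synergy_cv <- function(x, digits = 3, ...) {
  cat(sprintf("Fivefold cross-validation (%d folds)\n", length(x$folds)))
  m <- cbind(mean = round(x$mean, digits), sd = round(x$sd, digits))
  print(m)
  cat("\nHeld-out test report:\n")
  print(x$test, digits = digits)
  invisible(x)
}
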