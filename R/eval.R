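# Dataset construction and evaluation: Loewe-score labeling, stratified
# train/test + cross-validation splitting, pair-order augmentation, and the
# full classification metric set.

#' Label triplets by their Loewe additivity score
#'
#' Combinations scoring above 10 are synergistic (1), below 0 antagonistic
#' (0); scores in the dead zone \[0, 10\] are too close to additivity to
#' call and are discarded (`NA`).
#'
#' @param score Numeric vector of Loewe synergy scores.
#' @return Integer vector: 1, 0, or `NA` (discard). `NaN` scores are an
#'   error.
#' @export
#' @examples
#' label_by_loewe(c(15.2, -3, 5))  # 1, 0, NA
label_by_loewe <- function(score) {
  if (!is.numeric(score)) stop("'score' must be numeric", call. = FALSE)
  if (any(is.nan(score)))
    stop("Loewe score is NaN at position(s): ",
         paste(which(is.nan(score)), collapse = ", "), call. = FALSE)
  out <- rep(NA_integer_, length(score))
  out[score > 10] <- 1L
  out[score < 0] <- 0L
  out
}

#' Stratified train/test split with cross-validation folds
#'
#' Splits labeled samples 90/10 into a training and test portion, stratified
#' by label, and partitions the training portion into `n_folds` near-equal
#' stratified folds. The result is a disjoint cover of the input and is
#' deterministic given the seed.
#'
#' @param samples Data.frame with a `label` column (0/1).
#' @param seed Integer seed.
#' @param test_frac Test fraction (default 0.1).
#' @param n_folds Number of cross-validation folds of the training portion.
#' @return A list with `train` and `test` data.frames and `folds`, a list
#'   of integer row-index vectors into `train`.
#' @export
split_dataset <- function(samples, seed = 1L, test_frac = 0.1, n_folds = 5L) {
  stopifnot(is.data.frame(samples), "label" %in% names(samples))
  if (nrow(samples) < 10L) stop("need at least 10 samples", call. = FALSE)
  n <- nrow(samples)
  with_seed(seed, {
    test_idx <- integer(0)
    fold_of_train <- integer(0)
    train_idx <- integer(0)
    for (lv in sort(unique(samples$label))) {
      rows <- sample(which(samples$label == lv))
      n_test <- round(test_frac * length(rows))
      test_idx <- c(test_idx, rows[seq_len(n_test)])
      rest <- rows[-seq_len(n_test)]
      if (n_test == 0L) rest <- rows
      train_idx <- c(train_idx, rest)
      fold_of_train <- c(fold_of_train, rep_len(seq_len(n_folds), length(rest)))
    }
    ord <- sample(length(train_idx))  # decouple row order from label blocks
    train_idx <- train_idx[ord]
    fold_of_train <- fold_of_train[ord]
    folds <- split(seq_along(train_idx), fold_of_train)
    names(folds) <- NULL
    for (f in seq_along(folds)) {
      labs <- samples$label[train_idx[folds[[f]]]]
      if (length(unique(labs)) < 2L)
        warning(sprintf("fold %d contains a single class", f))
    }
    list(train = samples[train_idx, , drop = FALSE],
         test = samples[test_idx, , drop = FALSE],
         folds = folds)
  })
}

#' Augment triplets with their swapped drug order
#'
#' Every (drug A, drug B, cell) sample emits a (drug B, drug A, cell) twin
#' with the same label, so training sees both orders of each pair and the
#' learned function becomes approximately order-invariant.
#'
#' @param samples Data.frame with `drug_a` and `drug_b` columns.
#' @return Data.frame with `2 * nrow(samples)` rows.
#' @export
augment_order <- function(samples) {
  stopifnot(all(c("drug_a", "drug_b") %in% names(samples)))
  swapped <- samples
  swapped$drug_a <- samples$drug_b
  swapped$drug_b <- samples$drug_a
  out <- rbind(samples, swapped)
  rownames(out) <- NULL
  out
}

# Midrank AUROC: rank-sum form, equal to all-pairs concordance with half
# credit for ties.
.auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve by threshold integration: step
# summation of precision against recall increments at each distinct score,
# descending (the average-precision convention).
.aupr <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))          # tie groups share a threshold
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels)
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for synergy predictions
#'
#' Thresholds predicted probabilities at 0.5 into a confusion table and
#' reports accuracy, sensitivity (TPR), specificity (TNR), balanced
#' accuracy, precision and Cohen's kappa, plus threshold-free AUROC
#' (midrank convention) and AUPR (threshold-step integration).
#'
#' @param scores Predicted synergy-class probabilities.
#' @param labels 0/1 true labels; both classes must be present.
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_report` list with `auroc`, `aupr`, `acc`, `bacc`,
#'   `prec`, `tpr`, `tnr`, `kappa` and the confusion counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("AUROC undefined: labels contain a single class", call. = FALSE)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  tpr <- tp / (tp + fn)
  tnr <- tn / (fp + tn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e < 1) (acc - p_e) / (1 - p_e) else 0
  structure(list(
    auroc = .auroc(scores, labels), aupr = .aupr(scores, labels),
    acc = acc, bacc = (tpr + tnr) / 2, prec = prec, tpr = tpr, tnr = tnr,
    kappa = kappa, tp = tp, fp = fp, tn = tn, fn = fn, n = n),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Synergy classification report\n")
  m <- unlist(x[c("auroc", "aupr", "acc", "bacc", "prec", "tpr", "tnr",
                  "kappa")])
  print(round(m, digits))
  cat(sprintf("confusion (n=%d): TP=%d FP=%d TN=%d FN=%d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Order-swap sensitivity of a trained model
#'
#' Predicts every triplet in both drug orders, (A, B, cell) and
#' (B, A, cell), and reports the Pearson correlation between the two
#' probability vectors — a measure of how order-invariant the learned
#' function is.
#'
#' @param model A `synergy_model`.
#' @param samples Triplet data.frame (>= 2 rows).
#' @return A list with `pearson_r` and `scores`, a data.frame of the paired
#'   predictions for plotting.
#' @export
order_sensitivity <- function(model, samples) {
  if (nrow(samples) < 2L)
    stop("need at least 2 samples for a correlation", call. = FALSE)
  p_ab <- predict(model, samples)
  swapped <- samples
  swapped$drug_a <- samples$drug_b
  swapped$drug_b <- samples$drug_a
  p_ba <- predict(model, swapped)
  r <- if (stats::sd(p_ab) == 0 && stats::sd(p_ba) == 0 &&
           all(p_ab == p_ba)) 1
       else stats::cor(p_ab, p_ba)
  list(pearson_r = r,
       scores = data.frame(prob_ab = p_ab, prob_ba = p_ba))
}
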