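# Labeling, splitting, augmentation and the metric set.

test_that("Loewe thresholding applies the >10 / <0 rule with a dead zone", {
  expect_equal(label_by_loewe(c(15.2, -3, 5)), c(1L, 0L, NA_integer_))
  expect_equal(label_by_loewe(c(10, 0, 10.0001, -0.0001)),
               c(NA_integer_, NA_integer_, 1L, 0L))
  expect_error(label_by_loewe(c(1, NaN)), "NaN")
  expect_error(label_by_loewe("high"), "numeric")
})

test_that("stratified split is a disjoint cover with balanced folds", {
  set.seed(1)
  samples <- data.frame(id = 1:100, label = rep(c(0, 1), 50))
  sp <- split_dataset(samples, seed = 5)
  expect_equal(nrow(sp$test), 10L)
  expect_equal(vapply(sp$folds, length, integer(1)), rep(18L, 5))
  # disjoint cover
  all_ids <- c(sp$test$id, sp$train$id)
  expect_setequal(all_ids, samples$id)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_equal(anyDuplicated(unlist(sp$folds)), 0L)
  # per-fold prevalence within one sample of global 0.5
  for (f in sp$folds) {
    labs <- sp$train$label[f]
    expect_lte(abs(sum(labs) - length(labs) / 2), 1)
  }
  # determinism
  sp2 <- split_dataset(samples, seed = 5)
  expect_identical(sp$train$id, sp2$train$id)
  expect_identical(sp$folds, sp2$folds)
  # different seed shuffles
  sp3 <- split_dataset(samples, seed = 6)
  expect_false(identical(sp$train$id, sp3$train$id))
})

test_that("order augmentation doubles, swaps, and is an involution", {
  trip <- tiny_triplets()
  aug <- augment_order(trip)
  expect_equal(nrow(aug), 2L * nrow(trip))
  second <- aug[(nrow(trip) + 1):nrow(aug), ]
  expect_equal(second$drug_a, trip$drug_b)
  expect_equal(second$drug_b, trip$drug_a)
  expect_equal(second$label, trip$label)
  # swapping the swapped half recovers the original
  back <- augment_order(second)[seq_len(nrow(trip)) + nrow(trip), ]
  expect_equal(back$drug_a, trip$drug_a, ignore_attr = TRUE)
})

test_that("metrics reproduce the worked confusion table", {
  # TP=40, FP=10, TN=40, FN=10 -> everything 0.8, kappa 0.6
  labels <- c(rep(1, 40), rep(1, 10), rep(0, 40), rep(0, 10))
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.1, 40), rep(0.9, 10))
  m <- compute_metrics(scores, labels)
  expect_equal(m$tp, 40); expect_equal(m$fp, 10)
  expect_equal(m$tn, 40); expect_equal(m$fn, 10)
  expect_equal(m$acc, 0.8)
  expect_equal(m$tpr, 0.8); expect_equal(m$tnr, 0.8)
  expect_equal(m$bacc, 0.8); expect_equal(m$prec, 0.8)
  expect_equal(m$kappa, 0.6, tolerance = 1e-12)
})

test_that("perfect and constant predictors hit their closed forms", {
  labels <- rep(c(0, 1), 20)
  perfect <- labels
  m <- compute_metrics(perfect, labels)
  for (k in c("auroc", "aupr", "acc", "bacc", "prec", "tpr", "tnr", "kappa"))
    expect_equal(m[[k]], 1, tolerance = 1e-12)
  # constant predictor on a balanced set: acc 0.5, kappa 0
  mc <- compute_metrics(rep(0.3, 40), labels)
  expect_equal(mc$acc, 0.5)
  expect_equal(mc$kappa, 0, tolerance = 1e-12)
  expect_equal(mc$auroc, 0.5, tolerance = 1e-12)  # all ties, half credit
})

test_that("AUROC equals all-pairs concordance and the external check", {
  set.seed(7)
  for (k in 1:3) {
    n <- 200
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.45)
    m <- compute_metrics(scores, labels)
    expect_equal(m$auroc, auroc_bruteforce(scores, labels), tolerance = 1e-9)
  }
  # independent library cross-check on one draw
  scores <- runif(150); labels <- rbinom(150, 1, 0.5)
  m <- compute_metrics(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auroc, ref, tolerance = 1e-9)
})

test_that("bacc identity and kappa bounds hold on random confusion tables", {
  set.seed(8)
  for (k in 1:30) {
    tp <- sample(0:30, 1); fp <- sample(0:30, 1)
    tn <- sample(0:30, 1); fn <- sample(0:30, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    labels <- c(rep(1, tp + fn), rep(0, tn + fp))
    scores <- c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
    m <- compute_metrics(scores, labels)
    expect_equal(m$bacc, (m$tpr + m$tnr) / 2, tolerance = 1e-9)
    expect_gte(m$kappa, -1); expect_lte(m$kappa, 1)
  }
})

test_that("degenerate metric inputs raise errors", {
  expect_error(compute_metrics(c(0.1, 0.9), c(1, 1)), "single class")
  expect_error(compute_metrics(c(0.1), c(1, 0)), "length")
  expect_error(compute_metrics(c(0.1, 0.2), c(1, 2)), "0/1")
})
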