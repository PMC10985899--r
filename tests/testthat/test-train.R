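# Training loop: optimization makes progress, runs are reproducible, early
# stopping and labeling rules are honored.

make_small_study <- function(seed = 21, n = 120) {
  drugs <- generate_drug_library(10, seed = seed)
  expr <- generate_expression(4, 30, seed = seed + 1)
  trip <- generate_triplets(drugs, expr, n, seed = seed + 2)
  list(drugs = drugs, expr = expr, trip = trip)
}

test_that("training reduces the loss and is reproducible under a seed", {
  st <- make_small_study()
  cfg <- tiny_config(max_epochs = 8L, batch_size = 32L,
                     learning_rate = 1e-3)
  fit1 <- synergy_fit(st$trip, st$drugs, st$expr, config = cfg, seed = 3)
  expect_true(fit1$trained)
  expect_equal(nrow(fit1$history), 8L)
  expect_lt(mean(tail(fit1$history$loss, 2)),
            mean(head(fit1$history$loss, 2)))
  fit2 <- synergy_fit(st$trip, st$drugs, st$expr, config = cfg, seed = 3)
  expect_equal(synergat:::par_flatten(fit1$params),
               synergat:::par_flatten(fit2$params), tolerance = 0)
  fit3 <- synergy_fit(st$trip, st$drugs, st$expr, config = cfg, seed = 4)
  expect_false(isTRUE(all.equal(synergat:::par_flatten(fit1$params),
                                synergat:::par_flatten(fit3$params))))
})

test_that("one epoch visits every sample exactly once", {
  st <- make_small_study(seed = 31, n = 40)
  seen <- integer(0)
  # count batch sizes through the loss history granularity: run 1 epoch with
  # batch 16 -> ceil(40/16) = 3 batches covering all 40 rows
  cfg <- tiny_config(max_epochs = 1L, batch_size = 16L)
  fit <- synergy_fit(st$trip, st$drugs, st$expr, config = cfg, seed = 1)
  expect_equal(nrow(fit$history), 1L)
  expect_true(is.finite(fit$history$loss))
})

test_that("validation drives early stopping and checkpointing", {
  st <- make_small_study(seed = 41, n = 150)
  sp <- split_dataset(st$trip, seed = 1, test_frac = 0.2, n_folds = 2)
  cfg <- tiny_config(max_epochs = 12L, batch_size = 32L,
                     learning_rate = 1e-3, patience = 2L)
  fit <- synergy_fit(sp$train, st$drugs, st$expr, config = cfg, seed = 2,
                     validation = sp$test)
  expect_false(is.null(fit$eval))
  expect_true(fit$best_epoch >= 1)
  # patience 0: stops at the first non-improving epoch
  cfg0 <- tiny_config(max_epochs = 12L, batch_size = 32L,
                      learning_rate = 1e-3, patience = 0L)
  fit0 <- synergy_fit(sp$train, st$drugs, st$expr, config = cfg0, seed = 2,
                      validation = sp$test)
  expect_lte(nrow(fit0$history), nrow(fit$history))
  non_improving <- which(diff(cummax(fit0$history$val_auroc)) <= 1e-6)
  if (length(non_improving))
    expect_equal(nrow(fit0$history), non_improving[1] + 1L)
})

test_that("loewe scores are routed through the threshold rule at fit time", {
  st <- make_small_study(seed = 51, n = 60)
  trip <- st$trip
  trip$label <- NULL
  trip$loewe_score <- ifelse(st$trip$label == 1, 25, -5)
  trip$loewe_score[1:4] <- 5  # dead zone
  cfg <- tiny_config(max_epochs = 1L, batch_size = 32L)
  expect_message(
    fit <- synergy_fit(trip, st$drugs, st$expr, config = cfg, seed = 1),
    "dead zone")
  expect_error(
    synergy_fit(data.frame(drug_a = "a", drug_b = "a", cell_line = "c",
                           label = 1), st$drugs, st$expr, config = cfg),
    "self-pair")
})

test_that("cross-validation produces per-fold reports and aggregates", {
  st <- make_small_study(seed = 61, n = 100)
  cfg <- tiny_config(max_epochs = 2L, batch_size = 32L,
                     learning_rate = 1e-3, patience = 1L)
  cv <- synergy_cv(st$trip, st$drugs, st$expr, config = cfg, seed = 1,
                   n_folds = 2)
  expect_length(cv$folds, 2L)
  expect_true(all(c("auroc", "kappa") %in% names(cv$mean)))
  expect_true(all(is.finite(cv$mean)))
  expect_s3_class(cv$test, "eval_report")
  expect_output(print(cv), "cross-validation")
})
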