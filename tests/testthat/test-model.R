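# Model assembly: analytic gradients against finite differences, prediction
# invariants, attention reports, order sensitivity, S3 surface.

test_that("analytic gradients match central finite differences", {
  model <- tiny_model(kl_alpha = 0.7, kl_alpha_learnable = TRUE)
  trip <- tiny_triplets()
  idx <- synergat:::.resolve_triplets(model, trip)
  loss_fn <- function(m) {
    set.seed(42)
    synergat:::.train_step(m, idx, rate = 0.3,
                           alpha = synergat:::.model_alpha(m))$loss
  }
  set.seed(42)
  st <- synergat:::.train_step(model, idx, rate = 0.3,
                               alpha = synergat:::.model_alpha(model))
  g <- synergat:::par_flatten(st$grads)
  flat <- synergat:::par_flatten(model$params)
  skel <- model$params
  set.seed(9)
  pick <- c(sample(length(flat) - 1L, 40), length(flat))  # include KL weight
  h <- 1e-5
  for (i in pick) {
    up <- flat; up[i] <- up[i] + h
    dn <- flat; dn[i] <- dn[i] - h
    mu <- model; mu$params <- synergat:::par_unflatten(up, skel)
    md <- model; md$params <- synergat:::par_unflatten(dn, skel)
    num <- (loss_fn(mu) - loss_fn(md)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("predictions are normalized probabilities and deterministic", {
  model <- tiny_model()
  trip <- tiny_triplets()
  p <- predict(model, trip)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(model, trip))
  Z <- predict(model, trip, type = "logits")
  P <- exp(Z) / rowSums(exp(Z))
  expect_equal(P[, 2], p, tolerance = 1e-9)
  cls <- predict(model, trip, type = "class")
  expect_equal(cls, as.integer(p > 0.5))
})

test_that("unknown identifiers and malformed triplets are rejected", {
  model <- tiny_model()
  bad <- data.frame(drug_a = "dX", drug_b = "d2", cell_line = "cell01")
  expect_error(predict(model, bad), "unknown drug/cell id")
  expect_error(predict(model, data.frame(drug_a = "d1")), "lack column")
})

test_that("attention report rows are per-atom and normalized per drug", {
  model <- tiny_model()
  trip <- tiny_triplets()[1:2, ]
  rep_df <- attention_report(model, trip)
  # benzene (d2) contributes 6 rows per slot it occupies
  b_rows <- rep_df[rep_df$drug_id == "d2" & rep_df$triplet_id == 1, ]
  expect_equal(nrow(b_rows), 6L)
  expect_equal(unique(b_rows$symbol), "C")
  for (tid in unique(rep_df$triplet_id)) for (slot in c("A", "B")) {
    s <- rep_df$score[rep_df$triplet_id == tid & rep_df$drug_slot == slot]
    expect_equal(sum(s), 1, tolerance = 1e-6)
  }
})

test_that("a constructed symmetric architecture gives order correlation 1", {
  # Identity fusion (gates closed onto an identity carry) and a head whose
  # first-layer weights are identical across the two drug blocks make the
  # network exactly symmetric in its drug arguments.
  model <- tiny_model(mfic_identity_q = TRUE)
  K <- model$config$embedding_dim
  for (i in seq_along(model$params$mfic$layers)) {
    model$params$mfic$layers[[i]]$gate$W[] <- 0
    model$params$mfic$layers[[i]]$gate$b[] <- -1e9
  }
  W1 <- model$params$head$W1
  W1[(K + 1):(2 * K), ] <- W1[1:K, ]  # drug blocks share weights
  model$params$head$W1 <- W1
  os <- order_sensitivity(model, tiny_triplets())
  expect_equal(os$pearson_r, 1, tolerance = 1e-9)
  expect_equal(os$scores$prob_ab, os$scores$prob_ba, tolerance = 1e-9)
  expect_error(order_sensitivity(model, tiny_triplets()[1, ]), "at least 2")
})

test_that("the fitted-model S3 surface behaves", {
  model <- tiny_model()
  expect_output(print(model), "synergy model")
  expect_output(print(model), "trained: no")
  trip <- tiny_triplets()
  r <- residuals(model, newdata = trip)
  p <- predict(model, trip)
  expect_equal(sign(r), sign(trip$label - p))
  sim <- simulate(model, nsim = 3, seed = 1, newdata = trip)
  expect_equal(dim(sim), c(nrow(trip), 3L))
  expect_true(all(unlist(sim) %in% 0:1))
  expect_identical(coef(model), model$params)
})

test_that("expression transforms follow the configured policy", {
  drugs <- data.frame(drug_id = c("a", "b"), smiles = c("CCO", "CC"))
  pos <- matrix(c(0, 3), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  m_auto <- synergy_init(drugs, pos, config = tiny_config(cell_transform = "auto"))
  expect_equal(unname(m_auto$cell_mat["c1", ]), log2(c(0, 3) + 1))
  neg <- pos; neg[1, 1] <- -2
  m_auto2 <- synergy_init(drugs, neg, config = tiny_config(cell_transform = "auto"))
  expect_equal(unname(m_auto2$cell_mat["c1", ]), c(-2, 3))
  expect_error(
    synergy_init(drugs, neg, config = tiny_config(cell_transform = "log2")),
    "non-negative")
})
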