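# Cross-drug attention aggregation: score normalization, pooling algebra,
# readout normalization, pair-loop oracle, invariances.

test_that("degenerate embeddings give the closed-form scores", {
  p <- with_seed(1, init_aagam_params(4))
  # all-zero embeddings: tanh(0) logits, uniform softmax
  E0 <- matrix(0, 3, 4)
  expect_equal(unname(cross_attention_scores(E0, matrix(0, 2, 4), p)),
               rep(1 / 3, 3), tolerance = 1e-12)
  # single-atom self drug: softmax of one element
  E1 <- matrix(rnorm(4), 1, 4)
  expect_equal(unname(cross_attention_scores(E1, matrix(rnorm(8), 2, 4), p)), 1.0)
})

test_that("scores are strictly positive and sum to one", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- init_aagam_params(5)
    ES <- matrix(rnorm(5 * sample(1:8, 1)), ncol = 5)
    EO <- matrix(rnorm(5 * sample(1:8, 1)), ncol = 5)
    s <- cross_attention_scores(ES, EO, p)
    expect_equal(sum(s), 1, tolerance = 1e-6)
    expect_true(all(s > 0))
  }
})

test_that("attention pooling is the score-weighted value sum", {
  p <- with_seed(2, init_aagam_params(3))
  E <- matrix(c(1, 0, 2, -1, 3, 0.5, 0, 1, -2), 3, 3, byrow = TRUE)
  s <- c(0.5, 0.3, 0.2)
  V <- E %*% p$Wv
  hand <- 0.5 * V[1, ] + 0.3 * V[2, ] + 0.2 * V[3, ]
  expect_equal(attention_pool(E, s, p), hand, tolerance = 1e-12)
  # one atom: g is the value-projected row itself
  expect_equal(attention_pool(E[1, , drop = FALSE], 1, p), drop(V[1, ]),
               tolerance = 1e-12)
  # uniform scores: mean of value rows
  expect_equal(attention_pool(E, rep(1 / 3, 3), p), colMeans(V),
               tolerance = 1e-12)
})

test_that("readout layer-normalizes the residual mean", {
  E <- matrix(rnorm(12), 3, 4)
  g <- rnorm(4)
  G <- graph_readout(E, g)
  u <- colMeans(E) + g
  expect_equal(G, (u - mean(u)) / sqrt(mean((u - mean(u))^2) + 1e-5),
               tolerance = 1e-12)
  expect_equal(mean(G), 0, tolerance = 1e-9)
  # all-zero input maps to the zero vector under the eps-guarded norm
  expect_equal(graph_readout(matrix(0, 2, 4), rep(0, 4)), rep(0, 4))
})

test_that("full aggregation matches the nested-loop oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    d <- 4
    p <- init_aagam_params(d)
    EA <- matrix(rnorm(d * sample(2:6, 1)), ncol = d)
    EB <- matrix(rnorm(d * sample(2:6, 1)), ncol = d)
    orc <- aagam_oracle(EA, EB, p)
    s <- cross_attention_scores(EA, EB, p)
    expect_equal(s, orc$scores, tolerance = 1e-6, ignore_attr = TRUE)
    g <- attention_pool(EA, s, p)
    expect_equal(g, orc$g, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(graph_readout(EA, g), orc$G, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("aggregation is invariant to atom relabeling of either drug", {
  set.seed(11)
  p <- init_aagam_params(4)
  EA <- matrix(rnorm(20), 5, 4); EB <- matrix(rnorm(16), 4, 4)
  base <- graph_readout(EA, attention_pool(EA, cross_attention_scores(EA, EB, p), p))
  for (k in 1:5) {
    pa <- sample(5); pb <- sample(4)
    EAp <- EA[pa, ]; EBp <- EB[pb, ]
    G <- graph_readout(EAp, attention_pool(EAp, cross_attention_scores(EAp, EBp, p), p))
    expect_equal(G, base, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("scores for one drug respond to the partner (asymmetry)", {
  set.seed(12)
  p <- init_aagam_params(4)
  EA <- matrix(rnorm(12), 3, 4)
  EB1 <- matrix(rnorm(16), 4, 4)
  EB2 <- matrix(rnorm(16), 4, 4)
  s1 <- cross_attention_scores(EA, EB1, p)
  s2 <- cross_attention_scores(EA, EB2, p)
  expect_gt(max(abs(s1 - s2)), 1e-6)
})

test_that("width mismatches are configuration errors", {
  p <- with_seed(1, init_aagam_params(4))
  expect_error(cross_attention_scores(matrix(0, 2, 4), matrix(0, 2, 5), p),
               "width")
  expect_error(cross_attention_scores(matrix(0, 2, 3), matrix(0, 2, 3), p),
               "width")
  expect_error(graph_readout(matrix(0, 2, 4), rep(0, 3)), "width")
})
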