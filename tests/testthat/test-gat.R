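# Graph-attention encoder: normalization, closed-form cases, independence
# from the loop-based oracle, equivariance.

test_that("attention degenerates correctly on trivial graphs", {
  # isolated node: softmax over the self-loop alone
  g1 <- smiles_to_graph("C")
  p <- with_seed(1, init_gat_layer(atom_feature_info()$width, 4, num_heads = 2))
  a1 <- attention_coefficients(g1$node_features, g1, p)
  expect_equal(unname(a1[[1]][1, 1]), 1.0)

  # two connected nodes with identical feature rows: symmetry forces 0.5
  g2 <- smiles_to_graph("CC")  # ethane: two equivalent carbons
  a2 <- attention_coefficients(g2$node_features, g2, p)
  for (head in a2) expect_equal(as.numeric(head), rep(0.5, 4), tolerance = 1e-12)
})

test_that("attention rows are stochastic on random graphs", {
  for (seed in 1:8) {
    g <- random_graph(sample(2:8, 1), seed = seed)
    p <- with_seed(seed, init_gat_layer(ncol(g$node_features), 5, num_heads = 3))
    for (head in attention_coefficients(g$node_features, g, p)) {
      expect_equal(unname(rowSums(head)), rep(1, g$num_atoms), tolerance = 1e-6)
      expect_true(all(head >= 0 & head <= 1))
    }
  }
})

test_that("zero weights give sigma(0) everywhere and closed single-node form", {
  g <- smiles_to_graph("CCO")
  p <- with_seed(2, init_gat_layer(ncol(g$node_features), 4, num_heads = 2))
  pz <- p
  for (m in seq_along(pz$heads)) pz$heads[[m]]$W[] <- 0
  out <- gat_layer(g$node_features, g, pz)
  expect_equal(as.numeric(out), rep(0, length(out)))  # elu(0) = 0

  # single node, single head: h' = act(W' h) through the self-loop only
  g1 <- smiles_to_graph("C")
  p1 <- with_seed(3, init_gat_layer(ncol(g1$node_features), 4, num_heads = 1,
                                    activation = "identity"))
  out1 <- gat_layer(g1$node_features, g1, p1)
  expect_equal(as.numeric(out1),
               as.numeric(g1$node_features %*% p1$heads[[1]]$W),
               tolerance = 1e-12)
})

test_that("layer and two-layer stack match the loop-based oracle", {
  for (seed in 1:6) {
    g <- random_graph(sample(2:6, 1), seed = 100 + seed)
    d <- ncol(g$node_features)
    p1 <- with_seed(seed, init_gat_layer(d, 4, num_heads = 2))
    p2 <- with_seed(seed + 50,
                    init_gat_layer(8, 3, num_heads = 2, combine = "average",
                                   activation = "identity"))
    expect_equal(gat_layer(g$node_features, g, p1),
                 gat_layer_oracle(g$node_features, g, p1), tolerance = 1e-6,
                 ignore_attr = TRUE)
    enc <- encode_drug(g, list(p1, p2))
    two <- gat_layer_oracle(gat_layer_oracle(g$node_features, g, p1), g, p2)
    expect_equal(enc, two, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("encode_drug is permutation-equivariant", {
  g <- random_graph(6, seed = 42)
  d <- ncol(g$node_features)
  layers <- with_seed(9, list(
    init_gat_layer(d, 4, num_heads = 2),
    init_gat_layer(8, 5, num_heads = 2, combine = "average",
                   activation = "identity")))
  E <- encode_drug(g, layers)
  for (k in 1:10) {
    perm <- with_seed(k, sample(g$num_atoms))
    gp <- permute_graph(g, perm)
    Ep <- encode_drug(gp, layers)
    expect_equal(Ep[perm, , drop = FALSE], E, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("misconfiguration and degenerate inputs raise errors", {
  g <- smiles_to_graph("CCO")
  p <- with_seed(1, init_gat_layer(5, 4))  # wrong input width
  expect_error(gat_layer(g$node_features, g, p), "width")
  expect_error(encode_drug(g, list()), "at least one")
})
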