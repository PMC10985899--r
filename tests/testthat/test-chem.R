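# SMILES parsing and atom featurization.

test_that("small molecules parse to the expected graphs", {
  g1 <- smiles_to_graph("C")
  expect_equal(g1$num_atoms, 1L)
  expect_equal(nrow(g1$edges), 0L)

  g2 <- smiles_to_graph("CCO")
  expect_equal(g2$num_atoms, 3L)
  expect_equal(nrow(g2$edges), 2L)
  expect_setequal(g2$atom_symbols, c("C", "O"))

  g3 <- smiles_to_graph("c1ccccc1")
  expect_equal(g3$num_atoms, 6L)
  expect_equal(nrow(g3$edges), 6L)
  expect_true(all(g3$aromatic))
})

test_that("atom descriptors carry hand-checked valence arithmetic", {
  # methane: no heavy neighbors, four hydrogens, not aromatic
  m <- smiles_to_graph("C")
  expect_equal(m$degree, 0L)
  expect_equal(m$n_hydrogens, 4L)
  expect_false(any(m$aromatic))

  # ethanol oxygen: one heavy neighbor, one hydrogen
  e <- smiles_to_graph("CCO")
  o <- which(e$atom_symbols == "O")
  expect_equal(e$degree[o], 1L)
  expect_equal(e$n_hydrogens[o], 1L)

  # benzene carbon: two heavy neighbors, one hydrogen, aromatic
  b <- smiles_to_graph("c1ccccc1")
  expect_true(all(b$degree == 2L))
  expect_true(all(b$n_hydrogens == 1L))
})

test_that("feature matrix has constant width and valid one-hot blocks", {
  info <- atom_feature_info()
  for (smi in c("C", "CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O")) {
    X <- smiles_to_graph(smi)$node_features
    expect_equal(ncol(X), info$width)
    # exactly one element indicator per atom
    sym_block <- X[, seq_len(info$widths[["symbol"]]), drop = FALSE]
    expect_true(all(rowSums(sym_block) == 1))
  }
  # out-of-vocabulary element lands in the "other" slot, not an error
  sn <- smiles_to_graph("C[Si](C)C")
  other_col <- atom_feature_info()$widths[["symbol"]]
  si <- which(sn$atom_symbols == "Si")
  expect_equal(unname(sn$node_features[si, other_col]), 1)
})

test_that("featurization is deterministic and degree sums match edges", {
  for (smi in c("CCO", "c1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C")) {
    a <- smiles_to_graph(smi)
    b <- smiles_to_graph(smi)
    expect_identical(a$node_features, b$node_features)
    expect_identical(a$edges, b$edges)
    expect_equal(sum(a$degree), 2L * nrow(a$edges))
  }
})

test_that("different spellings of one molecule give isomorphic graphs", {
  pairs <- list(c("CCO", "OCC"),
                c("c1ccccc1O", "Oc1ccccc1"),
                c("CC(=O)O", "OC(C)=O"))
  for (p in pairs) {
    a <- smiles_to_graph(p[1]); b <- smiles_to_graph(p[2])
    expect_equal(a$num_atoms, b$num_atoms)
    expect_equal(nrow(a$edges), nrow(b$edges))
    # same multiset of descriptor rows
    sort_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
    expect_equal(sort_rows(a$node_features), sort_rows(b$node_features),
                 ignore_attr = TRUE)
  }
})

test_that("invalid input is rejected with informative errors", {
  expect_error(smiles_to_graph(""), "non-empty")
  expect_error(smiles_to_graph("   "), "non-empty")
  expect_error(smiles_to_graph("xy((z"), "cannot parse SMILES")
  expect_error(featurize_atoms(list()), "molecular_graph")
})

test_that("drug tables read from csv and from bare smiles lines", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,smiles", "a,CCO", "b,c1ccccc1"), path)
  df <- read_drug_table(path)
  expect_equal(df$drug_id, c("a", "b"))

  path2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "CC(C)O"), path2)
  df2 <- read_drug_table(path2)
  expect_equal(nrow(df2), 2L)
  expect_equal(df2$smiles[2], "CC(C)O")
})
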