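# Shared fixtures and independent brute-force oracles. The oracles are
# written as explicit per-node/per-pair loops so they share no code path
# with the package's matrix implementations.

# Build a molecular_graph directly (no SMILES), for random-graph property
# tests: a random spanning tree plus optional extra edges.
random_graph <- function(n, seed, p_extra = 0.3) {
  set.seed(seed)
  edges <- if (n > 1L)
    cbind(from = sample(seq_len(n - 1L)), to = 2:n)
  else matrix(integer(0), ncol = 2L)
  if (n > 1L) {
    edges <- t(apply(edges, 1L, function(e) c(min(e), max(e))))
    colnames(edges) <- c("from", "to")
  }
  if (n > 2L) {
    for (k in seq_len(max(0L, rpois(1L, p_extra * n)))) {
      e <- sort(sample(n, 2L))
      if (!any(edges[, 1L] == e[1L] & edges[, 2L] == e[2L]))
        edges <- rbind(edges, e)
    }
  }
  syms <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  g <- structure(list(
    smiles = sprintf("<random graph %d>", seed),
    num_atoms = n, atom_symbols = syms, edges = edges,
    bond_orders = rep(1L, nrow(edges)),
    degree = tabulate(c(edges), nbins = n),
    n_hydrogens = sample(0:3, n, replace = TRUE),
    implicit_valence = sample(0:3, n, replace = TRUE),
    aromatic = sample(c(TRUE, FALSE), n, replace = TRUE)),
    class = "molecular_graph")
  g$node_features <- featurize_atoms(g)
  g
}

# Relabel the atoms of a graph by a permutation: new index perm[i] holds
# old atom i.
permute_graph <- function(g, perm) {
  inv <- order(perm)
  edges <- g$edges
  if (nrow(edges) > 0L) {
    edges <- cbind(from = perm[edges[, 1L]], to = perm[edges[, 2L]])
    edges <- t(apply(edges, 1L, function(e) c(min(e), max(e))))
    colnames(edges) <- c("from", "to")
  }
  out <- g
  out$edges <- edges
  out$atom_symbols <- g$atom_symbols[inv]
  out$degree <- g$degree[inv]
  out$n_hydrogens <- g$n_hydrogens[inv]
  out$implicit_valence <- g$implicit_valence[inv]
  out$aromatic <- g$aromatic[inv]
  out$node_features <- g$node_features[inv, , drop = FALSE]
  out
}

# Independent GAT-layer oracle: explicit loops over nodes and neighborhoods.
gat_layer_oracle <- function(X, graph, params) {
  n <- nrow(X)
  nbr <- lapply(seq_len(n), function(i) i)  # self-loop
  if (nrow(graph$edges) > 0L) for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges[r, 1L]; b <- graph$edges[r, 2L]
    nbr[[a]] <- union(nbr[[a]], b); nbr[[b]] <- union(nbr[[b]], a)
  }
  act <- function(x) if (params$activation == "elu")
    ifelse(x > 0, x, exp(x) - 1) else x
  lk <- function(x) ifelse(x > 0, x, params$negative_slope * x)
  outs <- list()
  for (m in seq_along(params$heads)) {
    W <- params$heads[[m]]$W; a <- params$heads[[m]]$a
    hd <- ncol(W)
    Ht <- X %*% W
    out <- matrix(0, n, hd)
    for (i in seq_len(n)) {
      js <- nbr[[i]]
      e <- vapply(js, function(j)
        lk(sum(a * c(Ht[i, ], Ht[j, ]))), numeric(1))
      alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
      acc <- numeric(hd)
      for (k in seq_along(js)) acc <- acc + alpha[k] * Ht[js[k], ]
      out[i, ] <- act(acc)
    }
    outs[[m]] <- out
  }
  if (params$combine == "concat") do.call(cbind, outs)
  else Reduce(`+`, outs) / length(outs)
}

# Independent cross-attention oracle: nested loops over all atom pairs.
aagam_oracle <- function(E_self, E_other, params, ln_eps = 1e-5) {
  nS <- nrow(E_self); nO <- nrow(E_other)
  r <- numeric(nS)
  for (i in seq_len(nS)) for (j in seq_len(nO)) {
    kq <- sum((E_self[i, ] %*% params$Wk) * (E_other[j, ] %*% params$Wq))
    r[i] <- r[i] + tanh(kq)
  }
  s <- exp(r - max(r)); s <- s / sum(s)
  g <- numeric(ncol(E_self))
  for (i in seq_len(nS)) g <- g + s[i] * drop(E_self[i, ] %*% params$Wv)
  u <- colMeans(E_self) + g
  G <- (u - mean(u)) / sqrt(mean((u - mean(u))^2) + ln_eps)
  list(scores = s, g = g, G = G)
}

# All-pairs concordance AUROC with half credit for ties.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Small shared model fixture: tiny widths, real molecules.
tiny_config <- function(...) {
  args <- list(gat_layers = 2L, gat_heads = 2L, gat_hidden = 4L,
               embedding_dim = 6L, cell_hidden = 8L, head_hidden = 8L,
               mfic_depth = 2L, cell_transform = "none")
  args <- utils::modifyList(args, list(...))
  do.call(synergy_config, args)
}

tiny_model <- function(seed = 7L, n_cells = 3L, n_genes = 12L, ...) {
  drugs <- data.frame(
    drug_id = c("d1", "d2", "d3", "d4"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O", "c1ccncc1"),
    stringsAsFactors = FALSE)
  expr <- generate_expression(n_cells, n_genes, seed = seed + 1L)
  synergy_init(drugs, expr, config = tiny_config(...), seed = seed)
}

tiny_triplets <- function() {
  data.frame(drug_a = c("d1", "d2", "d3", "d1", "d4"),
             drug_b = c("d2", "d3", "d1", "d3", "d2"),
             cell_line = c("cell01", "cell02", "cell03", "cell02", "cell01"),
             label = c(1, 0, 1, 0, 1), stringsAsFactors = FALSE)
}
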