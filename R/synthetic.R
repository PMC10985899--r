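# Self-contained synthetic fixtures: a curated pool of small real drug-like
# molecules, Gaussian expression profiles, and triplets whose labels are
# planted through a logistic rule coupling a graph-visible drug property
# (aromatic-atom fraction) with a cell-expression feature (mean expression
# of a designated gene subset) — so learning the labels requires both the
# structural and the expression branch of the model.

# Curated SMILES pool: common solvents, drugs and heterocycles spanning
# aromatic fractions from 0 (alkanes, sugars) to 1 (pure aromatics). All
# parse to >= 1 heavy atom.
.smiles_pool <- function() {
  c(ethanol          = "CCO",
    propanol         = "CCCO",
    isopropanol      = "CC(C)O",
    acetone          = "CC(C)=O",
    butanone         = "CCC(C)=O",
    acetic_acid      = "CC(=O)O",
    diethyl_ether    = "CCOCC",
    acetonitrile     = "CC#N",
    chloroform       = "ClC(Cl)Cl",
    urea             = "NC(N)=O",
    acetamide        = "CC(N)=O",
    glycerol         = "OCC(O)CO",
    alanine          = "CC(N)C(=O)O",
    serine           = "OCC(N)C(=O)O",
    cyclohexane      = "C1CCCCC1",
    cyclohexanol     = "OC1CCCCC1",
    piperidine       = "C1CCNCC1",
    morpholine       = "C1COCCN1",
    dmso             = "CS(=O)C",
    ethylamine       = "CCN",
    benzene          = "c1ccccc1",
    toluene          = "Cc1ccccc1",
    phenol           = "Oc1ccccc1",
    aniline          = "Nc1ccccc1",
    pyridine         = "c1ccncc1",
    pyrrole          = "c1cc[nH]c1",
    furan            = "c1ccoc1",
    thiophene        = "c1ccsc1",
    imidazole        = "c1c[nH]cn1",
    naphthalene      = "c1ccc2ccccc2c1",
    styrene          = "C=Cc1ccccc1",
    anisole          = "COc1ccccc1",
    benzaldehyde     = "O=Cc1ccccc1",
    benzoic_acid     = "OC(=O)c1ccccc1",
    salicylic_acid   = "OC(=O)c1ccccc1O",
    aspirin          = "CC(=O)Oc1ccccc1C(=O)O",
    paracetamol      = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen        = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    caffeine         = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    nicotine         = "CN1CCCC1c1cccnc1")
}

#' Generate a drug library from the curated SMILES pool
#'
#' Draws `n_drugs` distinct molecules (without replacement) from a built-in
#' pool of 40 small, chemically valid structures. Deterministic per seed.
#'
#' @param n_drugs Number of drugs (at most the pool size).
#' @param seed Integer seed.
#' @return Data.frame with `drug_id` (the compound name) and `smiles`.
#' @export
generate_drug_library <- function(n_drugs = 30L, seed = 1L) {
  pool <- .smiles_pool()
  if (n_drugs > length(pool))
    stop(sprintf("n_drugs = %d exceeds the pool size (%d)", n_drugs,
                 length(pool)), call. = FALSE)
  pick <- with_seed(seed, sample(length(pool), n_drugs))
  data.frame(drug_id = names(pool)[pick], smiles = unname(pool[pick]),
             stringsAsFactors = FALSE)
}

#' Generate synthetic cell-line expression profiles
#'
#' Independent standard-normal entries on an already-normalized scale
#' (emulating centered log-expression over a landmark-style panel), with
#' systematic gene and cell identifiers. Deterministic per seed.
#'
#' @param n_cells Number of cell lines (columns).
#' @param n_genes Number of genes (rows; default 954, the landmark-panel
#'   size the model is configured around).
#' @param seed Integer seed.
#' @return Numeric matrix genes x cells with ids `g0001`... / `cell01`...
#' @export
generate_expression <- function(n_cells = 10L, n_genes = 954L, seed = 1L) {
  stopifnot(is_count(n_cells), is_count(n_genes))
  m <- with_seed(seed, matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("cell%02d", seq_len(n_cells))
  m
}

# Aromatic-atom fraction of each drug, the graph-visible half of the
# planted rule.
.aromatic_fraction <- function(drugs) {
  vapply(drugs$smiles, function(s) {
    g <- smiles_to_graph(s, featurize = FALSE)
    mean(g$aromatic)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate labeled synergy triplets with a planted signal
#'
#' Samples random drug pairs (A != B) and cell lines, then draws binary
#' labels from a logistic rule on interpretable features:
#' `P(synergistic) = sigmoid(signal_strength * (arom_A + arom_B + cell_feat
#' - center) + noise)`, where `arom` is each drug's aromatic-atom fraction,
#' `cell_feat` the mean expression of the first `n_rule_genes` genes, and
#' `center` the empirical mean of the feature sum (keeping prevalence near
#' 0.5). `signal_strength = 0` gives pure coin flips;
#' `signal_strength -> Inf` with `noise_sd = 0` makes labels a
#' deterministic function of the features.
#'
#' @param drugs Drug table from [generate_drug_library()].
#' @param expression Expression matrix from [generate_expression()].
#' @param n_triplets Number of samples.
#' @param signal_strength Logistic slope on the centered feature sum.
#' @param noise_sd Standard deviation of latent Gaussian noise added to the
#'   logit.
#' @param n_rule_genes Size of the designated gene subset driving the cell
#'   feature.
#' @param seed Integer seed.
#' @return Data.frame with `drug_a`, `drug_b`, `cell_line`, `label` and the
#'   generating probability `p_true`.
#' @export
generate_triplets <- function(drugs, expression, n_triplets = 1000L,
                              signal_strength = 8, noise_sd = 0.5,
                              n_rule_genes = 10L, seed = 1L) {
  stopifnot(nrow(drugs) >= 2L, ncol(expression) >= 1L, is_count(n_triplets))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  arom <- .aromatic_fraction(drugs)
  n_rule_genes <- min(n_rule_genes, nrow(expression))
  cell_feat <- colMeans(expression[seq_len(n_rule_genes), , drop = FALSE])
  with_seed(seed, {
    ai <- sample(nrow(drugs), n_triplets, replace = TRUE)
    bi <- vapply(ai, function(a) sample(setdiff(seq_len(nrow(drugs)), a), 1L),
                 integer(1))
    ci <- sample(ncol(expression), n_triplets, replace = TRUE)
    feat <- arom[ai] + arom[bi] + cell_feat[ci]
    z <- signal_strength * (feat - mean(feat)) +
      stats::rnorm(n_triplets, sd = noise_sd)
    p <- sigmoid(z)
    data.frame(drug_a = drugs$drug_id[ai], drug_b = drugs$drug_id[bi],
               cell_line = colnames(expression)[ci],
               label = stats::rbinom(n_triplets, 1L, p), p_true = p,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing a mutually consistent drug library,
#' expression matrix, gene panel and planted-signal triplet set, the whole
#' pipeline's test bed.
#'
#' @inheritParams generate_triplets
#' @param n_drugs,n_cells,n_genes Library sizes.
#' @param seed Integer seed (sub-seeds are derived per component).
#' @return A list with `drugs`, `expression`, `panel` (all gene ids) and
#'   `triplets`.
#' @export
generate_synergy_data <- function(n_drugs = 30L, n_cells = 10L,
                                  n_genes = 954L, n_triplets = 1000L,
                                  signal_strength = 8, noise_sd = 0.5,
                                  n_rule_genes = 10L, seed = 1L) {
  drugs <- generate_drug_library(n_drugs, seed = seed)
  expression <- generate_expression(n_cells, n_genes, seed = seed + 1L)
  triplets <- generate_triplets(drugs, expression, n_triplets,
                                signal_strength = signal_strength,
                                noise_sd = noise_sd,
                                n_rule_genes = n_rule_genes, seed = seed + 2L)
  list(drugs = drugs, expression = expression,
       panel = rownames(expression), triplets = triplets)
}
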