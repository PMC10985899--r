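# synergat

Graph-attention prediction of drug-combination synergy in R.

Anti-cancer drug combinations can kill tumor cells far beyond what either
drug achieves alone — or antagonize each other. Screening every pair across
every cell line is infeasible, so computational triage matters: given two
drug structures and a cell line's expression profile, predict whether the
combination is synergistic or antagonistic under the Loewe additivity
reference. `synergat` implements an end-to-end neural model of this task in
base R, together with the labeling, cross-validation, metric and
interpretability machinery around it, and a synthetic-data generator so the
whole pipeline runs and is tested without any external downloads. It is
aimed at computational pharmacologists and method developers who want a
transparent, dependency-light reference implementation whose every layer is
unit-tested against independent oracles.

## The model

For each drug, the SMILES string becomes a molecular graph (heavy atoms as
nodes, bonds as edges). Each atom *i* carries five descriptors — element,
heavy-atom degree, implicit valence, attached hydrogens, aromaticity —
encoded as one-hot blocks. A multi-head **graph attention network (GAT)**
updates atom embeddings; per head, the attention an atom *i* pays to a
neighbor *j* is

    α_ij = softmax_j( LeakyReLU( aᵀ [W h_i ‖ W h_j] ) ),   j ∈ N(i) ∪ {i}
    h_i' = ‖_m σ( Σ_j α_ij^m W^m h_j )

with heads concatenated on hidden layers and averaged at the last.

An **adaptive cross-drug aggregation** module pools each drug against its
partner. With E_A, E_B the final per-atom embeddings and learnable
projections W_k, W_q, W_v:

    S_A = softmax_i( Σ_j tanh( E_A W_k (E_B W_q)ᵀ )_ij )
    g_x = Σ_i S_A,i (E_A W_v)_i
    G_x = norm( mean_i(E_A) + g_x )          (feature-axis layer norm)

S_A is a per-atom importance distribution — the basis of the attention
reports — and G_x the graph-level embedding of drug A in the context of
drug B (symmetrically for G_y).

Cell lines are embedded from a TPM-normalized expression panel (default 954
genes) by a bias-free tanh MLP, `v = tanh(…tanh(c W⁰)… W^q)`. The fused
vector `F = [G_x ‖ G_y ‖ v]` passes through a stack of **gated interaction
(highway) layers**,

    y = g ⊙ relu(W F) + (1 − g) ⊙ Q F,    g = sigmoid(G F)

and a 2-layer softmax head yields P(synergistic).

Training minimizes the **dual-pass consistency objective**: each sample is
forwarded twice under independent dropout, giving ŷ₁, ŷ₂, and

    L = ½ [ CE(ŷ₁) + CE(ŷ₂) + α ( KL(ŷ₁‖ŷ₂) + KL(ŷ₂‖ŷ₁) ) ]

with Adam (default learning rate 1e-4, batch 128, dropout 0.1; a `"fast"`
preset uses 1e-3). Forward and backward passes are hand-written base-R
matrix algebra, verified in the test suite against central finite
differences and against loop-based brute-force oracles.

Labels follow the Loewe convention: score > 10 → synergistic, score < 0 →
antagonistic, the dead zone [0, 10] is discarded. Evaluation reports AUROC
(midrank), AUPR, accuracy, balanced accuracy, precision, sensitivity,
specificity and Cohen's kappa, with stratified 90/10 splitting and fivefold
cross-validation.

## Worked example

```r
library(synergat)

## a self-contained synthetic study: 30 drugs, 10 cell lines, 954 genes
dat <- generate_synergy_data(n_triplets = 1000, seed = 42)
sp  <- split_dataset(dat$triplets, seed = 42)     # 90/10 + 5 CV folds
va  <- sp$train[sp$folds[[1]], ]                  # early-stopping monitor
tr  <- sp$train[-sp$folds[[1]], ]

fit <- synergy_fit(tr, dat$drugs, dat$expression,
                   config = synergy_config(preset = "fast", max_epochs = 30),
                   seed = 42, validation = va)
fit
#> Drug-combination synergy model (graph attention + gated fusion)
#>   drugs: 30   cell lines: 10   gene panel: 954
#>   encoder: 2 GAT layer(s), 4 head(s), width 64 -> embedding 64
#>   fusion: depth-2 gated controller on width 192; head hidden 128
#>   parameters: 595,202   trained: yes (9 epochs)

compute_metrics(predict(fit, sp$test), sp$test$label)
#> Synergy classification report
#>  auroc   aupr    acc   bacc   prec    tpr    tnr  kappa
#> 0.9688 0.9609 0.9500 0.9500 0.9245 0.9800 0.9200 0.9000
#> confusion (n=100): TP=49 FP=4 TN=46 FN=1

head(attention_report(fit, sp$test[1:2, ]), 3)
#>     triplet_id drug_slot     drug_id atom_index symbol      score
#> C_1          1         A paracetamol          1      C 0.16536961
#> C_2          1         A paracetamol          2      C 0.09721913
#> O_3          1         A paracetamol          3      O 0.06872590
```

The held-out AUROC of 0.97 sits just at the Bayes ceiling of the planted
generative rule (~0.97), i.e. the model has recovered essentially all the
signal the generator put in. The attention report assigns each atom of each
drug a weight (summing to 1 per drug) quantifying its contribution to the
pair's pooled representation — the numeric form of substructure-importance
coloring.

A command-line interface wrapping the same functions is installed at
`inst/cli/synergat` (subcommands `simulate`, `featurize`, `train`,
`evaluate`, `predict`, `explain`).

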