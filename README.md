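# gipgru

Drug repositioning — finding new therapeutic indications for approved drugs
— can be framed as link prediction on the bipartite drug–disease network:
given a binary interaction matrix `I (m × n)`, a drug–drug similarity matrix
`S_D (m × m)` and a disease–disease similarity matrix `S_d (n × n)`, score
every unobserved (drug, disease) cell for how likely it is a true
association. `gipgru` implements a complete, tested pipeline for this
problem, aimed at computational biologists who want a reproducible baseline
they can run, probe and extend without any external downloads.

## The method

1. **Drug similarity sharpening.** Raw chemical similarities are mostly
   non-discriminative mid-range values. They are passed through a logistic
   adjustment

   `L(x) = 1 / (1 + exp(a·x + b))`,

   with defaults `a = −15`, `b = log 9999`, so `L(0) = 10⁻⁴` and
   `L(1) ≈ 0.997`: weak similarities are crushed toward zero, strong ones
   kept.

2. **Interaction-guided cluster boosting.** Drugs are clustered from their
   interaction profiles with a greedy cohesiveness-maximizing graph
   clustering (ClusterONE-style): a cluster `M` scores
   `f(M) = C_in / (C_in + C_bound + P(M))`, grown until no single add/remove
   improves it, with highly overlapping clusters merged. For drug pairs that
   land in a common module the raw similarity is restored
   (`max(S_adj, S_raw)`) — co-clustering is evidence the similarity was
   meaningful.

3. **Disease features via the GIP kernel.** The Gaussian interaction
   profile kernel over disease profiles (columns `y` of `I`):

   `K(d_i, d_j) = exp(−α ‖y_i − y_j‖²)`, `α = α′ / ((1/n) Σ ‖y_i‖²)`,

   with `α′ = 0.5`, averaged 50/50 with the phenotype similarity `S_d`.

4. **Pair features + TSVD.** Each (drug, disease) pair's feature vector is
   the concatenation of its drug and disease representation rows, reduced to
   64 dimensions by truncated SVD.

5. **GRU classifier.** A single-layer gated recurrent unit (update gate,
   reset gate, tanh candidate state) with 128 hidden units, dropout 0.25 on
   the final state, and a dense sigmoid head, trained with Adam on binary
   cross-entropy against positives (known interactions) and an equal number
   of sampled negative cells. The GRU, its backpropagation and Adam are
   implemented in the package and verified against finite-difference
   gradients and hand-evaluated gate equations.

Evaluation is tenfold cross-validation (per-fold accuracy, TPR, TNR, PPV,
MCC, ROC/AUC; mean ± sd over folds), with the interaction-derived features
recomputed per fold from training interactions only so held-out labels
cannot leak through the GIP kernel. A ranking mode scores all candidate
diseases for a query drug (or vice versa) for case-study style inspection.

## Worked example

```r
library(gipgru)

sim <- synthetic_benchmark(m = 100, n = 80, k_blocks = 4, seed = 42)
summary(sim$dataset)
#> drugs: 100
#> diseases: 80
#> known interactions: 737
#> density: 0.0921

cfg <- ddi_config(epochs = 30, hidden = 64, tsvd_dim = 32)
fit <- ddi_fit(sim$dataset, cfg, seed = 42)
fit
#> Drug-disease association model: 100 drugs x 80 diseases, 1474 training pairs
#> features: drug width 100 + disease width 80 -> TSVD 32; 1 drug clusters
#> GRU classifier: 64 hidden units, input width 32 (1 timestep)
#> trained 30 epochs, final mean loss 0.4473

cv <- ddi_cv(sim$dataset, cfg, folds = 10, seed = 42)
cv
#> 10-fold cross-validation (1474 pairs, seed 42)
#>         acc    tpr    tnr    ppv    mcc    auc
#> mean 0.8311 0.8460 0.8200 0.8255 0.6671 0.8282
#> sd   0.0353 0.0446 0.0762 0.0719 0.0702 0.0394
#> pooled AUC: 0.8233

ranked <- rank_candidates(fit, "DRUG0007")
print(ranked, n = 5)
#> Candidates ranked for drug 'DRUG0007' (80 candidates, 8 known)
#>   rank candidate     score known
#> 1    1   DIS0028 0.9020170     0
#> 2    2   DIS0051 0.8973056     1
#> 3    3   DIS0008 0.8942773     0
#> 4    4   DIS0014 0.8925218     0
#> 5    5   DIS0049 0.8828737     0
top_n_retrieval(ranked, 10)
#> [1] 4
```

The synthetic generator plants matched drug/disease blocks (interaction
probability 0.3 inside a matched block vs 0.02 outside), so the mean CV AUC
around 0.82 here is close to the best achievable given how much block
membership determines an interaction; on interactions permuted uniformly
over cells (`permute_interactions()`) the same pipeline drops to AUC ≈ 0.5,
as it should. The ranking output shows candidate diseases for one drug:
`known = 1` rows are its training-set indications (flagged, not removed),
and unflagged high-rank rows are the repositioning candidates.

Real benchmark matrices in the same three-matrix layout (tab-delimited
matrices plus ID sidecar files, or headered TSVs) load with
`load_benchmark()`; a thin command-line front end over the same functions is
installed at `inst/cli/gipgru.R` (`simulate`, `featurize`, `crossval`,
`rank`).

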