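---
title: "Predicting drug-disease associations with similarity fusion, GIP kernels and a GRU classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-disease associations with similarity fusion, GIP kernels and a GRU classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gipgru)
```

## The problem and the model

Drug repositioning asks which approved drugs might treat which diseases
beyond their current indications. `gipgru` treats this as supervised link
prediction on the bipartite drug–disease graph. The inputs are the standard
benchmark triple: a binary interaction matrix $I \in \{0,1\}^{m \times n}$
(rows drugs, columns diseases), a drug similarity matrix $S_D$ (typically
from 2D chemical fingerprints) and a disease similarity matrix $S_d$
(typically from phenotype annotations). The working assumption throughout is
the classic one: *similar drugs have similar indications*, and diseases with
similar interaction profiles behave similarly toward new drugs.

The pipeline, in the order `ddi_fit()` executes it:

**Logistic similarity adjustment.** Off-diagonal drug similarities pass
through $L(x) = 1/(1 + e^{a x + b})$. Most fingerprint similarities sit in an
uninformative mid/low range; with $a = -15$, $b = \log 9999$ the map pins
$L(0) = 10^{-4}$ and $L(1) \approx 0.997$, so only genuinely high
similarities survive. These defaults are the calibration used by the
similarity-adjustment lineage in repositioning models (the same two anchor
values reappear across that family); both are configurable
(`logistic_a`, `logistic_b`). The map is strictly increasing for $a < 0$, so
it never reorders similarities, only rescales them. Whether the *disease*
similarity should also be adjusted is genuinely open; the package defaults to
no, on the grounds that the disease side is already complemented by the GIP
kernel, and exposes the transform as a standalone function should a user
want it.

**Cohesiveness clustering and boosting.** Drugs are clustered *from their
interaction profiles*: the drug-axis GIP kernel (below) defines a weighted
graph (entries under `cluster_edge_floor = 0.1` dropped as noise edges), and
clusters grow greedily from unclustered high-degree seeds, accepting the
single vertex addition or removal that most increases the cohesiveness
$f(M) = C_{in}/(C_{in} + C_{bound} + P(M))$, stopping at a local maximum.
$P(M)$ is a per-node penalty (default: twice the mean positive edge weight,
scaling the penalty to the graph's weight regime) modelling unobserved
connections; clusters below `min_size = 3` members or weighted density 0.3
are discarded and clusters with overlap $\omega = |A \cap B|^2/(|A||B|)
\ge 0.8$ are merged. This is a faithful re-implementation of the published
greedy cohesiveness algorithm, not of any particular binary; exact parity
with other implementations is a non-goal. The algorithm is deterministic
(ties break by vertex index).

How cluster membership should feed back into similarity is not pinned down
by the method's verbal description, so the package makes one explicit,
switchable choice (`cluster_boost`): for drug pairs sharing at least one
cluster the adjusted similarity is restored to $\max(S_{adj}, S_{raw})$.
The rationale: the logistic map deliberately destroys mid-range values, but
a pair that co-clusters by *interaction* evidence probably had a meaningful
chemical similarity, so the raw value is the better feature. The operation
can only raise entries (never below $S_{adj}$, never above
$\max(S_{adj}, S_{raw})$).

**GIP kernel and disease fusion.** For diseases,
$K(d_i, d_j) = \exp(-\alpha\,\lVert y_i - y_j \rVert^2)$ over profile columns
$y$ of $I$, with bandwidth $\alpha = \alpha' \big/ \frac{1}{n}\sum_i
\lVert y_i\rVert^2$ and $\alpha' = 0.5$ (the conventional setting). The
normalization makes the kernel scale-free in the overall interaction
density. An all-zero $I$ leaves $\alpha$ undefined and is an error — GIP is
meaningless without any known interactions. The disease representation is
the convex combination $w\,K + (1-w)\,S_d$ with `disease_fusion_weight`
$w = 0.5$: the method names both phenotype similarity and GIP as disease
information without stating the combination, and an even average is the
neutral choice. The drug representation is the boosted similarity row;
appending drug-axis GIP rows is available (`use_drug_gip`) but off by
default, mirroring the division of labour in which similarity carries the
drug side and GIP the disease side.

**Pair features and TSVD.** A training pair's feature vector is the
concatenation of its drug row ($m$ wide) and disease row ($n$ wide). The
assembled pair matrix is reduced to `tsvd_dim = 64` columns by truncated
SVD. Whether the reduction belongs before or after concatenation is
ambiguous in the method's description ("combined two feature"); both orders
are supported (`tsvd_stage = "pairs"` default, `"representations"`, or
`"none"`), with the post-concatenation default because it lets the SVD
exploit drug–disease covariance. The sign of each right singular vector is
fixed (largest-magnitude component positive) so results are bit-reproducible
across runs; the basis `v` is stored in the fit so new pairs project into
the same space at prediction time.

**GRU classifier.** One gated recurrent unit layer with `hidden = 128`
units and a dense sigmoid head:

$$z_t = \sigma(W_z i_t + U_z h_{t-1} + b_z), \quad
  r_t = \sigma(W_r i_t + U_r h_{t-1} + b_r),$$
$$c_t = \tanh(W_h i_t + U_h (r_t \odot h_{t-1}) + b_h), \quad
  h_t = (1 - z_t) \odot h_{t-1} + z_t \odot c_t.$$

Two conventions deserve a note. First, the gate equations are sometimes
printed with $-b$; the package uses the conventional $+b$, which is the same
model under $b \mapsto -b$. Second, the printed binary cross-entropy in this
method family occasionally drops the $(1-t)$ factor from the first term;
the package implements the standard
$\mathcal{L}(t, p) = -\big((1-t)\log(1-p) + t\log p\big)$, clipped at
$p \in [10^{-7}, 1 - 10^{-7}]$, since the non-standard form is not a proper
loss for $t \in \{0,1\}$.

A flat feature vector has no intrinsic sequence, so `timesteps = 1` by
default: the GRU reads the whole vector in one step from $h_0 = 0$ (chunked
multi-step reading is available). With a zero initial state the recurrent
matrices and reset gate cancel algebraically in the single-step case, and
the implementation exploits that identity for speed — the computed values
are bit-identical to the general path. Dropout (0.25, inverted scaling) is
applied to the final hidden state before the dense head; "before the
activation layer" is the reading adopted for the ambiguous placement.
Training is minibatch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) with `epochs = 50`, `batch_size = 64`,
`learning_rate = 1e-3` — framework-default conventions, since the method
states the optimizer but not these values. Initialization is scaled-uniform
(Glorot) for $W_*$ and the head, orthogonal (sign-fixed QR) for $U_*$, zeros
for biases. The backward pass is hand-derived backpropagation through time;
the test suite checks it against central finite differences to $10^{-5}$
and the forward pass against scalar hand evaluation to $10^{-10}$. Training
is bitwise reproducible given a seed: initialization, shuffling and dropout
masks all derive from it, and the package restores the caller's RNG state
afterwards.

## Evaluation protocol

Positives are all known interactions; negatives are `negative_ratio = 1`
times as many zero cells, drawn uniformly without replacement — the standard
(and imperfect) assumption that unobserved pairs are non-interactions.
Negatives are drawn once per cross-validation run, not per fold, matching
the usual "divide all data into ten parts" protocol. The pooled sample is
shuffled into 10 near-equal folds (sizes differ by at most one; folds
partition the sample exactly).

**Leakage control.** The GIP kernel and the cluster boosting are functions
of $I$, so computing them on the full matrix would leak test labels into
training features. By default each fold recomputes both from the training
interactions only, with the fold's positive cells zeroed
(`refit_per_fold = TRUE`); the naive variant is available for comparison
(`--no-fold-refit` in the CLI). The method description itself is silent on
this point; the default is the defensible protocol.

Per fold the report carries accuracy, TPR, TNR, PPV and MCC at threshold
0.5 (the threshold is a package choice — the method does not state one — and
configurable), plus the ROC curve and AUC. AUC is computed as the
Mann–Whitney statistic via average ranks, exact under ties, and the suite
verifies it against an $O(n^2)$ pairwise oracle. Zero-denominator metrics
(PPV, MCC) return 0 with a `degenerate` flag rather than erroring. Summary
rows are the mean and *population* standard deviation over the 10 folds
(matching the mean ± sd convention of tenfold tables); whether a published
AUC is a per-fold mean or pooled is often unstated, so the report carries
both (`mean` of per-fold AUCs as the headline, `auc_pooled` alongside).

The ranking mode (`rank_candidates()`) scores all diseases for a query drug
(or all drugs for a disease) with the fitted model, sorts by descending
score with ties broken by candidate ID, and flags — rather than removes —
known interactions, since recovering confirmed indications near the top is
itself evidence of a sane model. `top_n_retrieval()` counts known
interactions in the top $N$.

## The synthetic generator: what it emulates and what it does not

`synthetic_benchmark()` generates the benchmark triple with planted
structure: drugs and diseases are assigned near-uniformly to `k_blocks`
matched blocks; interactions are Bernoulli(`p_in = 0.3`) inside matched
blocks and Bernoulli(`p_out = 0.02`) outside; similarities are
`sim_in = 0.8` within blocks, `sim_out = 0.1` between, plus symmetric
Gaussian noise (`sim_noise = 0.05`), clipped to $[0,1]$. The defaults
(m = 200, n = 150, k = 5) give ~2300 positives and a full tenfold CV in a
few minutes on one CPU; they are the package's reference study conditions.
The `sim_in`/`sim_out` gap is set wide enough that the logistic adjustment
separates it cleanly, which is exactly the regime the adjustment was
designed for.

This construction instantiates the method's own assumption — block
membership drives both similarity and interactions — so recovering high AUC
on it is a *parameter-recovery* check: the method works when its assumption
holds. Two caveats follow. First, with independent Bernoulli interactions
given blocks, block membership is all there is to learn; the best possible
test AUC is bounded by how well block match separates sampled positives
from sampled negatives (for the defaults this ceiling is ≈ 0.82, which the
pipeline approaches). Second, real benchmarks are nothing like
block-uniform: degree distributions are heavy-tailed, similarities are not
two-level, and negatives are unverified absences. Passing the synthetic
checks therefore demonstrates correctness of the machinery and
recoverability under the model's assumption — not real-data performance.
The complementary null control, `permute_interactions()`, shuffles the
1-cells uniformly while keeping similarities, and the pipeline's AUC on it
should (and does, in the acceptance run) fall to ≈ 0.5.

## Numerical choices and degenerate inputs

- Similarity validation: symmetry and unit diagonal to $10^{-10}$ absolute;
  entries slightly outside $[0,1]$ (rounding in public deposits) are clipped
  with a warning, asymmetry is an error. Matrices are re-symmetrized as
  $(S + S^\top)/2$ after transforms.
- The GIP kernel's squared distances are computed via the norm expansion
  with a clamp at 0 (guarding tiny negative round-off), the kernel is
  re-symmetrized and its diagonal set to exactly 1.
- `tsvd_reduce()` allows `k` above the numerical rank (trailing zero
  singular values) but errors for `k > min(dim)`. Requested `tsvd_dim` is
  capped at the feature-matrix dimensions at fit time.
- All-zero interaction matrices, single-class label vectors, empty cluster
  member sets, unknown query IDs and non-divisible timestep widths are
  errors with named causes; `top_n_retrieval` clamps over-long `n` with a
  warning instead, since the intent is unambiguous.
- Seeds: one global seed fans out to per-stage seeds through a fixed hash
  (`derive_seed`), so stages (negative sampling, fold assignment, per-fold
  model fits) can be reproduced in isolation; all derived seeds stay below
  $2^{31}$.

## Scale of the shipped checks

The unit and property tests run on small matrices (tens of rows) with
seeded loops; the end-to-end checks run the full default study conditions
(m = 200, n = 150, tenfold CV, plus the permuted null) — the sizes were
chosen so the complete suite finishes in a few minutes on a single CPU
while still exercising every stage at realistic dimensionality. The
acceptance script re-runs the same computations from scratch under a
user-supplied seed.

## Known limitations

- The optional SMILES path (Tanimoto over atom-pair descriptor sets via
  ChemmineR) will not bit-match fingerprints from other toolkits; the
  primary path is a precomputed similarity matrix.
- The cohesiveness clustering is a faithful re-implementation of the greedy
  algorithm, not a port of any reference binary; cluster boundaries can
  differ from other implementations on ties.
- Negative sampling treats unobserved pairs as negatives; ranking metrics
  on real data are accordingly pessimistic for drugs with undocumented
  indications.
- The GRU sees a feature *vector*, not a sequence; `timesteps > 1` chunks
  the vector arbitrarily and is provided for completeness, not because the
  chunks carry temporal meaning.
- Loading the published Fdataset/Cdataset deposits reproduces their
  documented dimensions via `load_benchmark()`, but those matrices are
  third-party data and are not shipped; the corresponding checks require
  placing the deposits under `inst/extdata/`.
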