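# Independent oracles used to cross-check the implementation.

# Confusion metrics by brute-force counting over reconstructed per-sample
# prediction/label vectors.
oracle_metrics <- function(TP, TN, FP, FN) {
  pred <- c(rep(1, TP), rep(0, TN), rep(1, FP), rep(0, FN))
  truth <- c(rep(1, TP), rep(0, TN), rep(0, FP), rep(1, FN))
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    acc = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else 0,
    tpr = if (tp + fn > 0) tp / (tp + fn) else 0,
    tnr = if (tn + fp > 0) tn / (tn + fp) else 0,
    ppv = if (tp + fp > 0) tp / (tp + fp) else 0,
    mcc = if (den > 0) num / den else 0
  )
}

# AUC by exhaustive pairwise comparison of every (positive, negative) pair.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Scalar GRU step written out in plain arithmetic (all parameters scalars).
oracle_gru_step_scalar <- function(Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh,
                                   i_t, h_prev) {
  sig <- function(x) 1 / (1 + exp(-x))
  z <- sig(Wz * i_t + Uz * h_prev + bz)
  r <- sig(Wr * i_t + Ur * h_prev + br)
  c <- tanh(Wh * i_t + Uh * (r * h_prev) + bh)
  list(z = z, r = r, c = c, h = (1 - z) * h_prev + z * c)
}

# Scalar parameter set for gru_step / gru_forward with chosen values.
scalar_params <- function(Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh,
                          dense_w = 1, dense_b = 0) {
  list(W_z = matrix(Wz, 1, 1), W_r = matrix(Wr, 1, 1), W_h = matrix(Wh, 1, 1),
       U_z = matrix(Uz, 1, 1), U_r = matrix(Ur, 1, 1), U_h = matrix(Uh, 1, 1),
       b_z = bz, b_r = br, b_h = bh, dense_w = dense_w, dense_b = dense_b)
}

# Zero out every parameter array of an initialized GRU.
zero_params <- function(p) {
  for (nm in names(p)) p[[nm]][] <- 0
  p
}

# Strip the bandwidth attribute a GIP kernel carries.
unclass_attr <- function(K) {
  attr(K, "bandwidth") <- NULL
  K
}

# Small valid dataset for I/O and pipeline tests.
toy_dataset <- function() {
  benchmark_dataset(
    drug_sim = matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3, 3),
    disease_sim = matrix(c(1, .3, .3, 1), 2, 2),
    interactions = matrix(c(1, 0, 0, 0, 1, 0), 3, 2),
    drugs = c("DB0001", "DB0002", "DB0003"),
    diseases = c("D100", "D200")
  )
}
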