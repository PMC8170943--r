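#' GIP kernel bandwidth from interaction profiles
#'
#' The Gaussian interaction profile (GIP) kernel bandwidth for one axis of
#' the interaction matrix: `alpha = alpha_prime / ((1/n) * sum_i ||y_i||^2)`,
#' where the `y_i` are the interaction profiles along that axis (rows of `I`
#' for drugs, columns for diseases) and `n` is their number. The default
#' `alpha_prime = 0.5` is the conventional calibration.
#'
#' @param I binary interaction matrix (drugs x diseases) or a
#'   [benchmark_dataset()].
#' @param axis `"diseases"` (profiles are columns of `I`) or `"drugs"`.
#' @param alpha_prime positive scale parameter.
#' @return A list with `alpha_prime`, `alpha`, `n_entities`.
#' @examples
#' I <- diag(2) # two diseases with unit profiles
#' gip_bandwidth(I, "diseases")$alpha # 0.5
#' @export
gip_bandwidth <- function(I, axis = c("diseases", "drugs"), alpha_prime = 0.5) {
  axis <- match.arg(axis)
  if (inherits(I, "benchmark_dataset")) I <- I$interactions
  I <- as.matrix(I)
  if (alpha_prime <= 0) fail("alpha_prime must be positive")
  sq <- if (axis == "diseases") colSums(I^2) else rowSums(I^2)
  msq <- mean(sq)
  if (msq == 0)
    fail("GIP bandwidth undefined: interaction matrix has no known interactions")
  list(alpha_prime = alpha_prime, alpha = alpha_prime / msq,
       n_entities = length(sq))
}

#' Gaussian interaction profile kernel
#'
#' Computes `K[i, j] = exp(-alpha * ||y_i - y_j||^2)` over the interaction
#' profiles along one axis of `I`, with `alpha` from [gip_bandwidth()]. The
#' result is a valid similarity matrix: symmetric, unit diagonal, entries in
#' (0, 1\], and positive semidefinite (a Gaussian kernel).
#'
#' @inheritParams gip_bandwidth
#' @return A k x k kernel matrix (k = entities along `axis`), with the
#'   bandwidth attached as attribute `bandwidth`.
#' @examples
#' I <- diag(2)
#' gip_kernel(I, "diseases")[1, 2] # exp(-1)
#' @export
gip_kernel <- function(I, axis = c("diseases", "drugs"), alpha_prime = 0.5) {
  axis <- match.arg(axis)
  if (inherits(I, "benchmark_dataset")) I <- I$interactions
  I <- as.matrix(I)
  bw <- gip_bandwidth(I, axis, alpha_prime)
  P <- if (axis == "diseases") t(I) else I  # profiles as rows
  sq <- rowSums(P^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  K <- exp(-bw$alpha * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  nm <- if (axis == "diseases") colnames(I) else rownames(I)
  dimnames(K) <- list(nm, nm)
  attr(K, "bandwidth") <- bw
  K
}

#' Per-disease feature representation
#'
#' Fuses the interaction-derived GIP kernel with the phenotype similarity
#' matrix: row `i` is `w * K_gip[i, ] + (1 - w) * S_d[i, ]`. `w = 1` gives
#' the pure GIP representation, `w = 0` the pure phenotype similarity.
#'
#' @param ds a [benchmark_dataset()].
#' @param K_gip disease-axis GIP kernel (n x n), e.g. from [gip_kernel()].
#' @param w fusion weight in \[0, 1\] on the GIP kernel.
#' @return An n x n matrix whose rows are per-disease feature vectors.
#' @export
disease_representation <- function(ds, K_gip, w = 0.5) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  K_gip <- as.matrix(K_gip)
  n <- length(ds$diseases)
  if (!all(dim(K_gip) == c(n, n))) fail("disease GIP kernel does not match disease index")
  if (w < 0 || w > 1) fail("fusion weight must be in [0, 1]")
  out <- w * K_gip + (1 - w) * ds$disease_sim
  dimnames(out) <- list(ds$diseases, ds$diseases)
  out
}

#' Per-drug feature representation
#'
#' Row `i` is the (boosted) drug similarity row; when `use_drug_gip` the
#' drug-axis GIP kernel row is appended, doubling the width.
#'
#' @param ds a [benchmark_dataset()].
#' @param S_boosted drug similarity matrix to use as the representation
#'   (m x m), typically [boost_with_clusters()] output.
#' @param use_drug_gip append drug-axis GIP features computed from
#'   `ds$interactions`.
#' @return An m x width matrix whose rows are per-drug feature vectors.
#' @export
drug_representation <- function(ds, S_boosted, use_drug_gip = FALSE) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  S_boosted <- as.matrix(S_boosted)
  m <- length(ds$drugs)
  if (!all(dim(S_boosted) == c(m, m))) fail("drug similarity does not match drug index")
  out <- S_boosted
  if (use_drug_gip) out <- cbind(out, gip_kernel(ds$interactions, "drugs"))
  rownames(out) <- ds$drugs
  out
}

#' Truncated singular value decomposition
#'
#' Rank-`k` SVD `X ~ U_k diag(d_k) V_k'` with a deterministic sign
#' convention: the largest-magnitude component of each right singular vector
#' is made positive. Columns are ordered by decreasing singular value.
#' `k` above the numerical rank is allowed (trailing singular values are ~0);
#' `k` above `min(dim(X))` is an error.
#'
#' @param X numeric matrix.
#' @param k number of singular triples to keep.
#' @param seed unused (the decomposition is deterministic); accepted so
#'   configurations carry one seed per stage.
#' @return A list with `scores` (`X %*% V_k` = `U_k diag(d_k)`, n x k), `d`
#'   (the k singular values), `v` (p x k right singular vectors for
#'   projecting new rows).
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' z <- tsvd_reduce(X, 2)
#' dim(z$scores) # 8 x 2
#' @export
tsvd_reduce <- function(X, k, seed = NULL) {
  X <- as.matrix(X)
  if (k < 1 || k > min(dim(X)))
    fail("k must be between 1 and min(dim(X)) = %d", min(dim(X)))
  s <- svd(X, nu = k, nv = k)
  v <- s$v
  u <- s$u
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  d <- s$d[seq_len(k)]
  scores <- u * rep(d, each = nrow(u))
  rownames(scores) <- rownames(X)
  list(scores = scores, d = d, v = v)
}

#' Assemble per-pair feature rows
#'
#' Builds the classifier input table: one row per (drug, disease) pair, the
#' feature vector being the concatenation of the drug's representation row
#' and the disease's representation row. Row order follows `pairs`.
#'
#' @param drug_repr m x p matrix of per-drug feature rows.
#' @param disease_repr n x q matrix of per-disease feature rows.
#' @param pairs two-column integer matrix of (drug index, disease index).
#' @param labels optional binary vector, one per pair (from the interaction
#'   matrix).
#' @return An object of class `pair_features`: list with `x` (features,
#'   one row per pair), `pairs`, `labels` (or `NULL`), `drug_ids`,
#'   `disease_ids`.
#' @export
assemble_pairs <- function(drug_repr, disease_repr, pairs, labels = NULL) {
  drug_repr <- as.matrix(drug_repr); disease_repr <- as.matrix(disease_repr)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs[, 1] < 1L | pairs[, 1] > nrow(drug_repr)))
    fail("drug index out of range in pairs")
  if (any(pairs[, 2] < 1L | pairs[, 2] > nrow(disease_repr)))
    fail("disease index out of range in pairs")
  if (!is.null(labels)) {
    if (length(labels) != nrow(pairs)) fail("labels length must match pairs")
    if (!all(labels %in% c(0, 1))) fail("labels must be binary")
    labels <- as.numeric(labels)
  }
  x <- cbind(drug_repr[pairs[, 1], , drop = FALSE],
             disease_repr[pairs[, 2], , drop = FALSE])
  rownames(x) <- NULL
  structure(
    list(x = x, pairs = pairs, labels = labels,
         drug_ids = rownames(drug_repr)[pairs[, 1]],
         disease_ids = rownames(disease_repr)[pairs[, 2]]),
    class = "pair_features"
  )
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("pair_features: %d pairs x %d features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else
                sprintf(" (%d positive / %d negative)",
                        sum(x$labels == 1), sum(x$labels == 0))))
  invisible(x)
}
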