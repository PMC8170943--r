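#' Logistic sharpening of a similarity matrix
#'
#' Applies the elementwise adjustment `L(x) = 1 / (1 + exp(a*x + b))` to every
#' off-diagonal entry. With the default calibration `a = -15`,
#' `b = log(9999)` the map sends non-discriminative low similarities close to
#' zero (`L(0) = 1e-4`) while keeping high similarities essentially intact
#' (`L(1) ~ 0.997`); it is strictly increasing in `x` for `a < 0`.
#'
#' @param S a symmetric similarity matrix (entries in \[0, 1\]).
#' @param a slope coefficient, must be non-zero.
#' @param b offset.
#' @param keep_diagonal force the diagonal back to 1 (default) rather than
#'   passing it through the logistic map.
#' @return The adjusted symmetric matrix, same dimnames as `S`.
#' @examples
#' S <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
#' logistic_adjust(S)
#' @export
logistic_adjust <- function(S, a = -15, b = log(9999), keep_diagonal = TRUE) {
  S <- as.matrix(S)
  if (a == 0) fail("logistic slope 'a' must be non-zero")
  out <- 1 / (1 + exp(a * S + b))
  if (keep_diagonal) diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  out
}

#' Cohesiveness of a vertex set in a weighted graph
#'
#' The cluster quality score used by cohesiveness-based graph clustering:
#' `f(M) = C_in(M) / (C_in(M) + C_bound(M) + P(M))`, where `C_in` is the total
#' weight of edges inside `M`, `C_bound` the total weight of edges crossing
#' the boundary of `M`, and the penalty `P(M) = penalty_per_node * |M|`
#' models unobserved connections. Always in \[0, 1\].
#'
#' @param weights symmetric non-negative weighted adjacency matrix (diagonal
#'   ignored).
#' @param members integer indices of the vertex set `M` (non-empty).
#' @param penalty_per_node non-negative per-node penalty.
#' @return The cohesiveness score.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
#' cohesiveness(W, c(1, 2), penalty_per_node = 0.5) # 1 / (1 + 1 + 1)
#' @export
cohesiveness <- function(weights, members, penalty_per_node = 0) {
  W <- as.matrix(weights)
  members <- as.integer(members)
  if (length(members) == 0L) fail("member set must be non-empty")
  if (any(members < 1L | members > nrow(W))) fail("member index out of range")
  diag(W) <- 0
  inside <- sum(W[members, members, drop = FALSE]) / 2
  bound <- sum(W[members, -members, drop = FALSE])
  pen <- penalty_per_node * length(members)
  denom <- inside + bound + pen
  if (denom == 0) return(0)
  inside / denom
}

#' Greedy cohesiveness-based graph clustering
#'
#' Detects (possibly overlapping) cohesive modules in a weighted similarity
#' graph by greedy seed growth: seeds are taken from still-unclustered
#' vertices in decreasing weighted-degree order; a cluster grows (or sheds) a
#' vertex whenever the step strictly increases [cohesiveness()]; grown
#' clusters below `min_size` or `min_density` are discarded, and clusters
#' whose overlap score `w(A,B) = |A \eqn{\cap}{n} B|^2 / (|A| |B|)` meets
#' `overlap_merge_threshold` are merged. Deterministic for a given input
#' (ties broken by vertex index); `seed` is accepted for interface stability.
#'
#' @param S symmetric similarity matrix; entries > 0 are edges, the diagonal
#'   is ignored.
#' @param penalty_per_node per-node penalty in the cohesiveness score;
#'   `NULL` (default) uses twice the mean positive edge weight.
#' @param min_size minimum cluster size retained (>= 2).
#' @param min_density minimum internal weighted density
#'   `2 C_in / (|M| (|M|-1))` retained.
#' @param overlap_merge_threshold overlap score at or above which two
#'   clusters are merged, in (0, 1\].
#' @param seed unused (algorithm is deterministic); kept so configurations
#'   carry one seed per stage.
#' @return A list of clusters, each a list with integer `members` and its
#'   `cohesiveness`.
#' @examples
#' S <- diag(8)
#' S[1:4, 1:4] <- 0.9; S[5:8, 5:8] <- 0.9; diag(S) <- 1
#' length(cluster_one(S)) # the two planted cliques
#' @export
cluster_one <- function(S, penalty_per_node = NULL, min_size = 3,
                        min_density = 0.3, overlap_merge_threshold = 0.8,
                        seed = NULL) {
  W <- as.matrix(S)
  if (nrow(W) != ncol(W)) fail("similarity matrix must be square")
  diag(W) <- 0
  W[W < 0] <- 0
  nv <- nrow(W)
  deg <- rowSums(W)
  if (is.null(penalty_per_node)) {
    pw <- W[W > 0]
    penalty_per_node <- if (length(pw)) 2 * mean(pw) else 0
  }
  if (min_size < 2) fail("min_size must be >= 2")

  clustered <- logical(nv)
  clusters <- list()
  for (s in order(-deg, seq_len(nv))) {
    if (clustered[s] || deg[s] == 0) next
    mem <- logical(nv); mem[s] <- TRUE
    inside <- 0
    # wsum[v] = total weight between v and current members
    wsum <- W[, s]
    repeat {
      size <- sum(mem)
      bound <- sum(wsum[!mem])
      f_cur <- coh_score(inside, bound, penalty_per_node * size)
      # candidate additions: external vertices attached to the cluster
      add <- which(!mem & wsum > 0)
      f_add <- if (length(add)) {
        coh_score(inside + wsum[add],
                  bound - wsum[add] + (deg[add] - wsum[add]),
                  penalty_per_node * (size + 1))
      } else numeric(0)
      # candidate removals (keep at least one vertex)
      rem <- if (size > 1L) which(mem) else integer(0)
      f_rem <- if (length(rem)) {
        coh_score(inside - wsum[rem],
                  bound + wsum[rem] - (deg[rem] - wsum[rem]),
                  penalty_per_node * (size - 1))
      } else numeric(0)
      best_add <- if (length(add)) which.max(f_add) else 0L
      best_rem <- if (length(rem)) which.max(f_rem) else 0L
      fa <- if (best_add) f_add[best_add] else -Inf
      fr <- if (best_rem) f_rem[best_rem] else -Inf
      eps <- 1e-12
      if (fa >= fr && fa > f_cur + eps) {
        v <- add[best_add]
        mem[v] <- TRUE
        inside <- inside + wsum[v]
        wsum <- wsum + W[, v]
      } else if (fr > f_cur + eps) {
        v <- rem[best_rem]
        mem[v] <- FALSE
        inside <- inside - wsum[v]
        wsum <- wsum - W[, v]
      } else break
    }
    members <- which(mem)
    size <- length(members)
    if (size < min_size) { clustered[s] <- TRUE; next }
    dens <- 2 * inside / (size * (size - 1))
    if (dens < min_density) { clustered[s] <- TRUE; next }
    clustered[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- members
  }

  clusters <- merge_overlapping(clusters, overlap_merge_threshold)
  lapply(clusters, function(mem) {
    list(members = mem,
         cohesiveness = cohesiveness(W, mem, penalty_per_node))
  })
}

coh_score <- function(inside, bound, pen) {
  denom <- inside + bound + pen
  out <- ifelse(denom > 0, inside / denom, 0)
  out
}

merge_overlapping <- function(clusters, threshold) {
  repeat {
    k <- length(clusters)
    if (k < 2L) return(clusters)
    merged <- FALSE
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        ov <- length(intersect(clusters[[i]], clusters[[j]]))^2 /
          (length(clusters[[i]]) * length(clusters[[j]]))
        if (ov >= threshold) {
          clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(clusters)
  }
}

#' Restore raw similarity for co-clustered pairs
#'
#' The logistic adjustment deliberately crushes mid-range similarities; for
#' drug pairs that the interaction-based clustering places in a common module
#' this is evidence the similarity was meaningful, so the raw value is
#' restored when larger: for pairs co-occurring in at least one cluster the
#' output entry is `max(S_adj, S_raw)`, elsewhere it is `S_adj`. The result
#' never drops below `S_adj` and never exceeds `pmax(S_adj, S_raw)`.
#'
#' @param S_raw the unadjusted similarity matrix.
#' @param S_adj the logistic-adjusted similarity matrix (same index).
#' @param clusters list of clusters as returned by [cluster_one()] (or bare
#'   integer vectors of member indices).
#' @return A symmetric unit-diagonal similarity matrix.
#' @export
boost_with_clusters <- function(S_raw, S_adj, clusters) {
  S_raw <- as.matrix(S_raw); S_adj <- as.matrix(S_adj)
  if (!all(dim(S_raw) == dim(S_adj))) fail("S_raw and S_adj must share dimensions")
  n <- nrow(S_adj)
  out <- S_adj
  for (cl in clusters) {
    mem <- if (is.list(cl)) cl$members else cl
    mem <- as.integer(mem)
    if (any(mem < 1L | mem > n)) fail("cluster member outside similarity index")
    out[mem, mem] <- pmax(out[mem, mem], S_raw[mem, mem])
  }
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(S_adj)
  out
}

#' Pairwise Tanimoto similarity from SMILES (optional path)
#'
#' Computes a drug-drug similarity matrix as pairwise Tanimoto coefficients
#' `|A n B| / |A u B|` over 2D atom-pair descriptor sets, for use when no
#' precomputed similarity matrix is available. SMILES are canonicalized
#' during parsing, so notation variants of the same molecule score 1.
#' Requires the suggested packages \pkg{ChemmineR} and \pkg{ChemmineOB};
#' results approximate, but do not bit-match, other fingerprint toolkits.
#' Unparseable records are skipped with a warning and listed in the
#' `skipped` attribute.
#'
#' @param smiles named character vector: names are drug IDs, values SMILES.
#' @return A similarity matrix over the parseable IDs, with attribute
#'   `skipped` naming dropped records.
#' @export
tanimoto_from_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    fail("tanimoto_from_smiles needs the suggested packages ChemmineR and ChemmineOB")
  if (is.null(names(smiles)) || anyDuplicated(names(smiles)))
    fail("smiles must be a named vector with unique IDs")
  ids <- names(smiles)
  aps <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    ap <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles[[i]]))
      if (length(sdf) != 1L) NULL else suppressMessages(ChemmineR::sdf2ap(sdf))
    }, error = function(e) NULL)
    if (!is.null(ap)) { aps[[i]] <- ap; ok[i] <- TRUE }
  }
  if (!any(ok)) fail("no parseable SMILES records")
  if (any(!ok))
    warning(sprintf("skipped unparseable SMILES: %s",
                    paste(ids[!ok], collapse = ", ")), call. = FALSE)
  keep_ids <- ids[ok]
  sets <- lapply(aps[ok], function(a) unique(ChemmineR::ap(a)[[1]]))
  k <- length(keep_ids)
  S <- matrix(1, k, k, dimnames = list(keep_ids, keep_ids))
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    un <- length(union(sets[[i]], sets[[j]]))
    S[i, j] <- S[j, i] <- if (un == 0) 0 else
      length(intersect(sets[[i]], sets[[j]])) / un
  }
  attr(S, "skipped") <- ids[!ok]
  S
}
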