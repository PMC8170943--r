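test_that("logistic adjustment matches its closed form and is monotone", {
  S <- matrix(c(1, 0, 0.5, 0, 1, 1, 0.5, 1, 1), 3, 3)
  # midpoint: a*x + b = 0
  expect_equal(logistic_adjust(S, a = -2, b = 1)[1, 3], 0.5)
  # default calibration: x = 0 -> exactly 1e-4; x = 1 -> ~0.99695
  adj <- logistic_adjust(S)
  expect_equal(adj[1, 2], 1 / (1 + 9999))
  expect_equal(adj[2, 3], 1 / (1 + exp(-15 + log(9999))), tolerance = 1e-12)
  expect_equal(adj[2, 3], 0.99695, tolerance = 1e-4)
  # diagonal handling
  expect_equal(diag(adj), rep(1, 3), ignore_attr = TRUE)
  adj2 <- logistic_adjust(S, keep_diagonal = FALSE)
  expect_equal(diag(adj2), rep(1 / (1 + exp(-15 + log(9999))), 3),
               ignore_attr = TRUE)
  # strict monotonicity in x for a < 0
  xs <- sort(runif(50))
  Sx <- diag(2)
  vals <- vapply(xs, function(x) {
    Sx[1, 2] <- Sx[2, 1] <- x
    logistic_adjust(Sx)[1, 2]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("cohesiveness matches direct evaluation and its monotonicity", {
  # isolated pair, one internal edge
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  expect_equal(cohesiveness(W, c(1, 2)), 1)
  # one boundary edge of equal weight splits the score
  W[2, 3] <- W[3, 2] <- 1
  expect_equal(cohesiveness(W, c(1, 2)), 0.5)
  # path a-b-c, M = {a, b}, penalty 0.5 per node
  expect_equal(cohesiveness(W, c(1, 2), penalty_per_node = 0.5), 1 / 3)
  expect_error(cohesiveness(W, integer(0)), "non-empty")

  # property: internal edges help, boundary edges hurt
  set.seed(7)
  for (rep in 1:20) {
    n <- 8
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
    M <- sample(n, 4)
    f0 <- cohesiveness(W, M, penalty_per_node = 0.3)
    expect_gte(f0, 0); expect_lte(f0, 1)
    Win <- W; ij <- sample(M, 2)
    Win[ij[1], ij[2]] <- Win[ij[2], ij[1]] <- Win[ij[1], ij[2]] + 0.5
    expect_gte(cohesiveness(Win, M, penalty_per_node = 0.3), f0)
    Wb <- W; out <- setdiff(seq_len(n), M)[1]
    Wb[M[1], out] <- Wb[out, M[1]] <- Wb[M[1], out] + 0.5
    expect_lte(cohesiveness(Wb, M, penalty_per_node = 0.3), f0)
  }
})

test_that("greedy clustering recovers planted modules", {
  # two disjoint 4-cliques
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 0.9; S[5:8, 5:8] <- 0.9; diag(S) <- 1
  cl <- cluster_one(S)
  expect_length(cl, 2)
  mems <- lapply(cl, `[[`, "members")
  expect_setequal(mems[[1]], 1:4)
  expect_setequal(mems[[2]], 5:8)
  expect_true(all(vapply(cl, `[[`, numeric(1), "cohesiveness") > 0))

  # edgeless graph
  expect_length(cluster_one(diag(10)), 0)

  # planted 3-block weighted graph: recovered blocks match by Jaccard
  set.seed(7)
  blocks <- rep(1:3, each = 10)
  W <- ifelse(outer(blocks, blocks, "=="),
              matrix(runif(900, 0.7, 0.9), 30, 30),
              matrix(rbinom(900, 1, 0.05) * 0.3, 30, 30))
  W <- (W + t(W)) / 2; diag(W) <- 1
  cl <- cluster_one(W, seed = 7)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (b in 1:3) {
    truth <- which(blocks == b)
    best <- max(vapply(cl, function(x) jac(x$members, truth), numeric(1)))
    expect_gte(best, 0.9)
  }
  # determinism
  cl2 <- cluster_one(W, seed = 7)
  expect_identical(cl, cl2)
})

test_that("cluster boosting restores raw similarity only where co-clustered", {
  set.seed(1)
  S_raw <- matrix(runif(25), 5, 5); S_raw <- (S_raw + t(S_raw)) / 2; diag(S_raw) <- 1
  S_adj <- logistic_adjust(S_raw)
  # no clusters: identity on S_adj
  expect_equal(boost_with_clusters(S_raw, S_adj, list()), S_adj)
  # everything in one cluster: elementwise max
  all_in <- boost_with_clusters(S_raw, S_adj, list(1:5))
  want <- pmax(S_adj, S_raw); diag(want) <- 1
  expect_equal(all_in, want)
  # a single co-clustered pair
  S_raw2 <- S_raw; S_raw2[1, 2] <- S_raw2[2, 1] <- 0.8
  S_adj2 <- S_adj; S_adj2[1, 2] <- S_adj2[2, 1] <- 0.1
  out <- boost_with_clusters(S_raw2, S_adj2, list(list(members = 1:2)))
  expect_equal(out[1, 2], 0.8)
  expect_equal(out[3:5, 3:5], S_adj2[3:5, 3:5])
  # bounds: never below S_adj, never above max(S_adj, S_raw)
  expect_true(all(out >= S_adj2 - 1e-12))
  expect_true(all(out <= pmax(S_adj2, pmax(S_raw2, diag(5))) + 1e-12))
  expect_error(boost_with_clusters(S_raw, S_adj, list(c(4, 9))), "outside")
})

test_that("Tanimoto similarity from SMILES behaves on knowns", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  sm <- c(eth1 = "CCO", eth2 = "OCC", benzene = "c1ccccc1")
  S <- suppressMessages(tanimoto_from_smiles(sm))
  expect_equal(diag(S), c(eth1 = 1, eth2 = 1, benzene = 1))
  # notation variants of ethanol canonicalize to the same descriptor set
  expect_equal(S["eth1", "eth2"], 1)
  # ethanol and benzene share no atom pairs
  expect_equal(S["eth1", "benzene"], 0)
  expect_warning(S2 <- suppressMessages(
    tanimoto_from_smiles(c(good = "CCO", bad = "not_a_smiles("))),
    "skipped")
  expect_equal(attr(S2, "skipped"), "bad")
})
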