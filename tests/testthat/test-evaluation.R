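test_that("negative sampling draws distinct zero cells reproducibly", {
  set.seed(1)
  I <- matrix(rbinom(20 * 15, 1, 0.2), 20, 15)
  n1 <- sum(I)
  neg <- sample_negatives(I, ratio = 1, seed = 5)
  expect_equal(nrow(neg), n1)
  expect_true(all(I[neg] == 0))
  expect_equal(anyDuplicated(neg), 0)
  expect_identical(neg, sample_negatives(I, ratio = 1, seed = 5))
  expect_false(identical(neg, sample_negatives(I, ratio = 1, seed = 6)))
  # fractional ratio floors
  expect_equal(nrow(sample_negatives(I, ratio = 0.5, seed = 1)),
               floor(0.5 * n1))
  # no zero cells
  expect_error(sample_negatives(matrix(1, 2, 2)), "zero cells")
})

test_that("confusion metrics equal the per-sample counting oracle", {
  m <- metrics_from_counts(3, 3, 1, 1)
  expect_equal(m$acc, 0.75)
  expect_equal(m$tpr, 0.75)
  expect_equal(m$tnr, 0.75)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$mcc, 0.5)
  # perfect classifier
  mp <- metrics_from_counts(10, 20, 0, 0)
  expect_equal(unlist(mp[c("acc", "tpr", "tnr", "ppv", "mcc")]),
               c(acc = 1, tpr = 1, tnr = 1, ppv = 1, mcc = 1))
  # degenerate denominators return 0 with the flag set
  md <- metrics_from_counts(0, 5, 0, 5)
  expect_equal(md$ppv, 0)
  expect_equal(md$mcc, 0)
  expect_true(md$degenerate)
  # random count vectors against the brute-force oracle
  set.seed(2)
  for (rep in 1:200) {
    cts <- rpois(4, 8)
    got <- metrics_from_counts(cts[1], cts[2], cts[3], cts[4])
    want <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(got[c("acc", "tpr", "tnr", "ppv", "mcc")], want)
  }
})

test_that("AUC equals the exhaustive pairwise statistic", {
  # perfectly separated
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # random sets, with ties, against the O(n^2) oracle
  set.seed(6)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    scores <- round(runif(n), 2) # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  s <- runif(50); l <- rbinom(50, 1, 0.5); l[1:2] <- c(0, 1)
  expect_equal(roc_auc(exp(3 * s) + 1, l)$auc, roc_auc(s, l)$auc)
  # ROC endpoints
  r <- roc_auc(s, l)$roc
  expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_error(roc_auc(s, rep(1, 50)), "both classes")
})

test_that("cross-validation folds partition the pairs near-equally", {
  sim <- synthetic_benchmark(m = 30, n = 24, k_blocks = 3, p_in = 0.5,
                             p_out = 0.05, seed = 2)
  cfg <- ddi_config(epochs = 2, hidden = 8, tsvd_dim = 10, cluster_boost = FALSE)
  cv <- ddi_cv(sim$dataset, cfg, folds = 10, seed = 2)
  N <- nrow(cv$pairs)
  sizes <- table(cv$fold_id)
  expect_length(sizes, 10)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), N)
  # no duplicated pair across folds (pairs are unique, folds partition)
  expect_equal(anyDuplicated(cv$pairs), 0)
  # report shape and ranges
  expect_equal(nrow(cv$per_fold), 10)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  expect_true(all(cv$mean >= -1 & cv$mean <= 1))
  # population sd over folds
  expect_equal(unname(cv$sd["acc"]),
               sqrt(mean((cv$per_fold$acc - mean(cv$per_fold$acc))^2)))
  # reproducible fold assignment and metrics
  cv2 <- ddi_cv(sim$dataset, cfg, folds = 10, seed = 2)
  expect_identical(cv$fold_id, cv2$fold_id)
  expect_identical(cv$per_fold, cv2$per_fold)
  # report files
  d <- file.path(tempdir(), "cvrep")
  write_cv_report(cv, d)
  expect_true(file.exists(file.path(d, "report.tsv")))
  expect_true(file.exists(file.path(d, "roc.csv")))
  tab <- read.delim(file.path(d, "report.tsv"))
  expect_equal(nrow(tab), 12) # 10 folds + mean + sd
})

test_that("candidate ranking honours scores, ties and known flags", {
  sim <- synthetic_benchmark(m = 25, n = 18, k_blocks = 2, p_in = 0.6,
                             p_out = 0.05, seed = 4)
  cfg <- ddi_config(epochs = 8, hidden = 8, tsvd_dim = 10, cluster_boost = FALSE)
  fit <- ddi_fit(sim$dataset, cfg, seed = 4)
  q <- sim$dataset$drugs[1]
  ranked <- rank_candidates(fit, q)
  expect_equal(nrow(ranked), 18)
  expect_equal(ranked$rank, 1:18)
  expect_true(all(diff(ranked$score) <= 0))
  expect_equal(sum(ranked$known),
               sum(sim$dataset$interactions[1, ]))
  expect_error(rank_candidates(fit, "NOPE"), "NOPE")

  # degenerate constant-score model: ranks fall back to candidate-ID order
  fit0 <- fit
  fit0$gru$params <- zero_params(fit0$gru$params)
  r0 <- rank_candidates(fit0, q)
  expect_equal(r0$candidate, sort(sim$dataset$diseases))

  # top-N retrieval
  expect_equal(top_n_retrieval(ranked, 18), sum(ranked$known))
  expect_warning(n_all <- top_n_retrieval(ranked, 50), "clamped")
  expect_equal(n_all, sum(ranked$known))
  oracle <- ranked
  oracle$known <- as.integer(oracle$score >= sort(oracle$score, decreasing = TRUE)[5])
  expect_equal(top_n_retrieval(oracle, 3), 3)
})

test_that("block partners of a query drug occupy the top ranks", {
  # one strong planted block out of eight: the query's matched-block
  # diseases should fill the top of the ranking
  sim <- synthetic_benchmark(m = 80, n = 80, k_blocks = 8, p_in = 0.6,
                             p_out = 0.02, seed = 13)
  cfg <- ddi_config(epochs = 30, hidden = 32, tsvd_dim = 32)
  fit <- ddi_fit(sim$dataset, cfg, seed = 13)
  q <- which.max(rowSums(sim$dataset$interactions))
  ranked <- rank_candidates(fit, sim$dataset$drugs[q])
  partners <- sim$dataset$diseases[
    sim$truth$disease_blocks == sim$truth$drug_blocks[q]]
  partner_ranks <- ranked$rank[ranked$candidate %in% partners]
  expect_lte(median(partner_ranks), 0.10 * nrow(ranked))
})

test_that("random-score retrieval matches the hypergeometric expectation", {
  set.seed(10)
  n_cand <- 60; n_known <- 12; topn <- 10
  counts <- replicate(200, {
    df <- data.frame(rank = 1:n_cand,
                     candidate = sprintf("C%02d", 1:n_cand),
                     score = runif(n_cand),
                     known = sample(c(rep(1L, n_known), rep(0L, n_cand - n_known))))
    df <- df[order(-df$score), ]; df$rank <- 1:n_cand
    class(df) <- c("ranked_list", "data.frame")
    top_n_retrieval(df, topn)
  })
  expected <- topn * n_known / n_cand
  se <- sqrt(topn * (n_known / n_cand) * (1 - n_known / n_cand)) / sqrt(200)
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.2)
})
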