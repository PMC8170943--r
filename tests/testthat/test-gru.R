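test_that("gru_step matches hand-evaluated gate equations", {
  p0 <- zero_params(gru_init(3, 4, seed = 1))
  st <- gru_step(p0, rep(0, 3), rep(0, 4))
  expect_equal(st$z, rep(0.5, 4))
  expect_equal(st$r, rep(0.5, 4))
  expect_equal(st$c, rep(0, 4))
  expect_equal(st$h, rep(0, 4))

  # scalar midpoint
  p <- scalar_params(1, 1, 0, 1, 1, 0, 1, 1, 0)
  expect_equal(gru_step(p, 0, 0)$z, 0.5)

  # scalar hand oracle across parameter settings
  set.seed(9)
  for (rep in 1:20) {
    v <- rnorm(9); i_t <- rnorm(1); h_prev <- rnorm(1)
    p <- scalar_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8], v[9])
    got <- gru_step(p, i_t, h_prev)
    want <- oracle_gru_step_scalar(v[1], v[2], v[3], v[4], v[5], v[6],
                                   v[7], v[8], v[9], i_t, h_prev)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("gate outputs stay in their ranges and h is a convex combination", {
  set.seed(4)
  for (rep in 1:20) {
    p <- gru_init(5, 6, seed = rep)
    i_t <- rnorm(5, sd = 3); h_prev <- rnorm(6, sd = 2)
    st <- gru_step(p, i_t, h_prev)
    expect_true(all(st$z > 0 & st$z < 1))
    expect_true(all(st$r > 0 & st$r < 1))
    expect_true(all(st$c > -1 & st$c < 1))
    expect_lte(max(abs(st$h)), max(max(abs(h_prev)), 1))
  }
})

test_that("forward pass composes steps and the dense sigmoid head", {
  # zero network outputs exactly 0.5
  p0 <- zero_params(gru_init(4, 3, seed = 1))
  expect_equal(gru_forward(p0, rnorm(4)), 0.5)

  # scalar toy equals the composed hand oracle
  p <- scalar_params(0.7, -0.3, 0.1, 0.5, 0.2, -0.1, 1.1, 0.4, 0.2,
                     dense_w = 1.5, dense_b = -0.25)
  x <- 0.8
  st <- oracle_gru_step_scalar(0.7, -0.3, 0.1, 0.5, 0.2, -0.1, 1.1, 0.4, 0.2,
                               x, 0)
  expect_equal(gru_forward(p, x), 1 / (1 + exp(-(1.5 * st$h - 0.25))),
               tolerance = 1e-10)

  # multi-timestep forward equals manual unrolling of gru_step
  p2 <- gru_init(3, 5, seed = 2)
  x2 <- rnorm(6)
  h <- rep(0, 5)
  h <- gru_step(p2, x2[1:3], h)$h
  h <- gru_step(p2, x2[4:6], h)$h
  want <- 1 / (1 + exp(-(sum(p2$dense_w * h) + p2$dense_b)))
  expect_equal(gru_forward(p2, x2, timesteps = 2), want, tolerance = 1e-12)

  # inference is deterministic (pure function of params and input)
  expect_identical(gru_forward(p2, x2, timesteps = 2),
                   gru_forward(p2, x2, timesteps = 2))
  expect_error(gru_forward(p2, rnorm(5), timesteps = 2), "divisible")
})

test_that("binary cross-entropy matches direct evaluation and is clipped", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_equal(bce_loss(1 - 1e-12, 1), 0, tolerance = 1e-6)
  expect_equal(bce_loss(0.8, 1), -log(0.8))
  expect_equal(bce_loss(0.8, 0), -log(0.2))
  expect_true(is.finite(bce_loss(0, 1)))
  expect_true(is.finite(bce_loss(1, 1)))
  expect_gte(bce_loss(runif(1), rbinom(1, 1, 0.5)), 0)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  p <- gru_init(4, 3, seed = 2)
  X <- matrix(rnorm(5 * 8), 5, 8) # 2 timesteps of width 4
  y <- c(1, 0, 1, 1, 0)
  fw <- gipgru:::gru_forward_batch(p, X, 2, keep_cache = TRUE)
  g <- gipgru:::gru_backward_batch(p, X, y, fw, 2, 0, NULL)
  h <- 1e-6
  for (nm in names(p)) {
    for (idx in seq_len(min(length(p[[nm]]), 5))) {
      pp <- p; pm <- p
      pp[[nm]][idx] <- pp[[nm]][idx] + h
      pm[[nm]][idx] <- pm[[nm]][idx] - h
      num <- (bce_loss(gipgru:::gru_forward_batch(pp, X, 2)$prob, y) -
                bce_loss(gipgru:::gru_forward_batch(pm, X, 2)$prob, y)) / (2 * h)
      expect_equal(g[[nm]][idx], num, tolerance = 1e-5)
    }
  }
})

test_that("training learns separable data and is seed-reproducible", {
  set.seed(3)
  n <- 200
  x <- matrix(rnorm(n * 6), n, 6)
  w <- c(2, -1.5, 1, 0, 0.5, -1)
  y <- as.numeric(drop(x %*% w) > 0)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  fit <- gru_train(x, y, hidden = 16, epochs = 60, dropout = 0,
                   batch_size = 32, seed = 3)
  acc <- mean((predict(fit, x) >= 0.5) == y)
  expect_gte(acc, 0.95)
  # loss decreases over early epochs
  expect_lt(fit$history[5], fit$history[1])

  # bitwise determinism
  fit2 <- gru_train(x, y, hidden = 16, epochs = 60, dropout = 0,
                    batch_size = 32, seed = 3)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)

  # zero epochs returns the initialization with empty history
  fit0 <- gru_train(x, y, hidden = 16, epochs = 0, seed = 3)
  expect_length(fit0$history, 0)
  expect_identical(fit0$params, gru_init(6, 16, seed = derive_seed(3, "init")))

  # single-class labels are rejected
  expect_error(gru_train(x, rep(1, n), hidden = 4, epochs = 1), "both classes")
})

test_that("prediction is consistent, equivariant and in (0,1)", {
  set.seed(8)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  fit <- gru_train(x, y, hidden = 8, epochs = 5, seed = 1)
  sc <- predict(fit, x)
  # matches row-by-row forward evaluation
  sc_rows <- vapply(seq_len(nrow(x)), function(i)
    gru_forward(fit$params, x[i, ]), numeric(1))
  expect_equal(sc, sc_rows, tolerance = 1e-12)
  # permutation equivariance
  perm <- sample(60)
  expect_equal(predict(fit, x[perm, ]), sc[perm])
  expect_true(all(sc > 0 & sc < 1))
  expect_error(predict(fit, x[, 1:3]), "width")
})
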