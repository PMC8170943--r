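#' One gated-recurrent-unit step
#'
#' Evaluates the GRU gate equations for a single input vector:
#' \deqn{z_t = sigmoid(W_z i_t + U_z h_{t-1} + b_z)}
#' \deqn{r_t = sigmoid(W_r i_t + U_r h_{t-1} + b_r)}
#' \deqn{c_t = tanh(W_h i_t + U_h (r_t \odot h_{t-1}) + b_h)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot c_t}
#' so the new state is a gatewise convex combination of the previous state
#' and the candidate: gates lie in (0, 1), the candidate in (-1, 1), and
#' `max(abs(h_t)) <= max(max(abs(h_prev)), 1)`.
#'
#' @param params GRU parameters, see [gru_init()].
#' @param i_t input vector (length = input width).
#' @param h_prev previous hidden state (length = hidden units).
#' @return A list with `h`, and the gate intermediates `z`, `r`, `c`.
#' @examples
#' p <- gru_init(input_dim = 1, hidden = 1, seed = 1)
#' p$W_z[] <- 0; p$U_z[] <- 0; p$b_z[] <- 0
#' gru_step(p, 0, 0)$z # sigmoid(0) = 0.5
#' @export
gru_step <- function(params, i_t, h_prev) {
  st <- gru_step_batch(params, matrix(i_t, nrow = 1), matrix(h_prev, nrow = 1))
  list(h = drop(st$H), z = drop(st$Z), r = drop(st$R), c = drop(st$C))
}

# Batched step: Xt (N x input), H (N x hidden). Returns new state + gates.
gru_step_batch <- function(p, Xt, H) {
  Z <- sigmoid(Xt %*% t(p$W_z) + H %*% t(p$U_z) +
                 rep(p$b_z, each = nrow(Xt)))
  R <- sigmoid(Xt %*% t(p$W_r) + H %*% t(p$U_r) +
                 rep(p$b_r, each = nrow(Xt)))
  C <- tanh(Xt %*% t(p$W_h) + (R * H) %*% t(p$U_h) +
              rep(p$b_h, each = nrow(Xt)))
  list(H = (1 - Z) * H + Z * C, Z = Z, R = R, C = C)
}

#' Initialize GRU + dense-head parameters
#'
#' Input-to-hidden matrices `W_*` use scaled-uniform (Glorot) initialization,
#' hidden-to-hidden matrices `U_*` are orthogonal (QR of a Gaussian matrix
#' with a deterministic sign fix), biases start at zero, and the dense head
#' is Glorot-initialized. Deterministic given `seed`.
#'
#' @param input_dim width of each timestep's input slice.
#' @param hidden number of hidden units.
#' @param seed integer seed.
#' @return A named list of parameters: `W_z, W_r, W_h` (hidden x input),
#'   `U_z, U_r, U_h` (hidden x hidden), `b_z, b_r, b_h` (hidden),
#'   `dense_w` (hidden), `dense_b` (scalar).
#' @export
gru_init <- function(input_dim, hidden, seed = 1) {
  with_seed(seed, {
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    ortho <- function(k) {
      A <- matrix(stats::rnorm(k * k), k, k)
      qrd <- qr(A)
      Q <- qr.Q(qrd)
      Q * rep(sign(diag(qr.R(qrd))), each = k)
    }
    list(
      W_z = glorot(hidden, input_dim), W_r = glorot(hidden, input_dim),
      W_h = glorot(hidden, input_dim),
      U_z = ortho(hidden), U_r = ortho(hidden), U_h = ortho(hidden),
      b_z = numeric(hidden), b_r = numeric(hidden), b_h = numeric(hidden),
      dense_w = drop(glorot(hidden, 1)), dense_b = 0
    )
  })
}

#' GRU forward pass to a probability
#'
#' Reshapes a flat feature vector into `timesteps` consecutive slices, rolls
#' them through [gru_step()] from a zero initial state, and maps the final
#' hidden state through a dense sigmoid head:
#' `p = sigmoid(dense_w . h_T + dense_b)`. Dropout (inverted scaling) is
#' applied to the final hidden state only during training
#' (`dropout_active = TRUE`); at inference the output is a pure function of
#' parameters and input.
#'
#' @param params GRU parameters, see [gru_init()].
#' @param x feature vector, or a matrix of feature rows.
#' @param timesteps number of slices; feature width must be divisible by it.
#' @param dropout dropout rate in \[0, 1).
#' @param dropout_active apply dropout (training mode).
#' @return Probabilities in (0, 1), one per input row.
#' @export
gru_forward <- function(params, x, timesteps = 1, dropout = 0,
                        dropout_active = FALSE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  mask <- NULL
  if (dropout_active && dropout > 0) {
    hdim <- length(params$dense_w)
    mask <- matrix(stats::rbinom(nrow(X) * hdim, 1, 1 - dropout),
                   nrow(X), hdim)
  }
  drop(gru_forward_batch(params, X, timesteps, dropout, mask)$prob)
}

# Full batched forward. `mask` NULL means inference. Returns prob (+ cache
# of per-step intermediates when keep_cache, for backpropagation).
# With a single timestep the initial state is zero, so the recurrent
# matrices and the reset gate drop out of the algebra exactly
# (H %*% U = 0, r * h_prev = 0, (1-z)*h_prev = 0); the one-step branch
# computes the identical quantities without those products.
gru_forward_batch <- function(p, X, timesteps, dropout = 0, mask = NULL,
                              keep_cache = FALSE) {
  N <- nrow(X); width <- ncol(X)
  if (width %% timesteps != 0)
    fail("feature width %d not divisible by timesteps %d", width, timesteps)
  step_w <- width %/% timesteps
  if (ncol(p$W_z) != step_w)
    fail("parameter input width %d does not match per-step width %d",
         ncol(p$W_z), step_w)
  hdim <- length(p$dense_w)
  cache <- if (keep_cache) vector("list", timesteps) else NULL
  if (timesteps == 1L) {
    Z <- sigmoid(X %*% t(p$W_z) + rep(p$b_z, each = N))
    C <- tanh(X %*% t(p$W_h) + rep(p$b_h, each = N))
    H <- Z * C
    if (keep_cache) cache[[1L]] <- list(Z = Z, C = C)
  } else {
    H <- matrix(0, N, hdim)
    for (t in seq_len(timesteps)) {
      cols <- ((t - 1L) * step_w + 1L):(t * step_w)
      st <- gru_step_batch(p, X[, cols, drop = FALSE], H)
      if (keep_cache) cache[[t]] <- list(H_prev = H, Z = st$Z, R = st$R,
                                         C = st$C, cols = cols)
      H <- st$H
    }
  }
  Hd <- if (!is.null(mask)) H * mask / (1 - dropout) else H
  prob <- sigmoid(drop(Hd %*% p$dense_w) + p$dense_b)
  list(prob = prob, H = H, Hd = Hd, cache = cache)
}

#' Binary cross-entropy loss
#'
#' The standard form `-( (1 - t) log(1 - p) + t log(p) )`, averaged over
#' elements for vector input. Predictions are clipped to
#' \[1e-7, 1 - 1e-7\] so the loss is always finite.
#'
#' @param p predicted probabilities.
#' @param t binary labels.
#' @return Mean loss (non-negative).
#' @examples
#' bce_loss(0.5, 1) # log(2)
#' @export
bce_loss <- function(p, t) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-((1 - t) * log(1 - p) + t * log(p)))
}

# Backward pass for one minibatch under mean BCE loss.
# Returns gradients with the same names/shapes as the parameters.
gru_backward_batch <- function(p, X, y, fw, timesteps, dropout, mask) {
  N <- nrow(X)
  hdim <- length(p$dense_w)
  dOut <- (fw$prob - y) / N                        # d loss / d (dense pre-activation)
  g <- list(
    W_z = matrix(0, hdim, ncol(p$W_z)), W_r = matrix(0, hdim, ncol(p$W_r)),
    W_h = matrix(0, hdim, ncol(p$W_h)),
    U_z = matrix(0, hdim, hdim), U_r = matrix(0, hdim, hdim),
    U_h = matrix(0, hdim, hdim),
    b_z = numeric(hdim), b_r = numeric(hdim), b_h = numeric(hdim),
    dense_w = drop(crossprod(fw$Hd, dOut)), dense_b = sum(dOut)
  )
  dH <- outer(dOut, p$dense_w)
  if (!is.null(mask)) dH <- dH * mask / (1 - dropout)
  if (timesteps == 1L) {
    # zero initial state: only W_z, W_h and their biases receive gradient
    cc <- fw$cache[[1L]]
    Z <- cc$Z; C <- cc$C
    dAc <- (dH * Z) * (1 - C^2)
    dAz <- (dH * C) * Z * (1 - Z)
    g$W_z <- crossprod(dAz, X); g$b_z <- colSums(dAz)
    g$W_h <- crossprod(dAc, X); g$b_h <- colSums(dAc)
    return(g)
  }
  for (t in rev(seq_len(timesteps))) {
    cc <- fw$cache[[t]]
    Xt <- X[, cc$cols, drop = FALSE]
    Hp <- cc$H_prev; Z <- cc$Z; R <- cc$R; C <- cc$C
    dZ <- dH * (C - Hp)
    dC <- dH * Z
    dAc <- dC * (1 - C^2)
    dAz <- dZ * Z * (1 - Z)
    dRH <- dAc %*% p$U_h
    dR <- dRH * Hp
    dAr <- dR * R * (1 - R)
    g$W_z <- g$W_z + crossprod(dAz, Xt)
    g$U_z <- g$U_z + crossprod(dAz, Hp)
    g$b_z <- g$b_z + colSums(dAz)
    g$W_r <- g$W_r + crossprod(dAr, Xt)
    g$U_r <- g$U_r + crossprod(dAr, Hp)
    g$b_r <- g$b_r + colSums(dAr)
    g$W_h <- g$W_h + crossprod(dAc, Xt)
    g$U_h <- g$U_h + crossprod(dAc, R * Hp)
    g$b_h <- g$b_h + colSums(dAc)
    dH <- dH * (1 - Z) + dRH * R + dAz %*% p$U_z + dAr %*% p$U_r
  }
  g
}

#' Train the GRU classifier
#'
#' Minibatch training with the Adam optimizer under mean binary
#' cross-entropy, dropout on the final hidden state, and per-epoch
#' reshuffling. Fully deterministic given `seed` (initialization, shuffling
#' and dropout masks all derive from it).
#'
#' @param x feature matrix (rows = samples) or a `pair_features` object with
#'   labels.
#' @param labels binary label vector (ignored when `x` is `pair_features`).
#' @param hidden hidden units (default 128).
#' @param dropout dropout rate on the final hidden state (default 0.25).
#' @param epochs training epochs (default 50); 0 returns the initialization.
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param timesteps GRU timesteps; feature width must be divisible by it.
#' @param seed integer seed.
#' @return An object of class `gru_fit`: list with `params`, `history`
#'   (mean training loss per epoch) and `config`.
#' @export
gru_train <- function(x, labels = NULL, hidden = 128, dropout = 0.25,
                      epochs = 50, batch_size = 64, learning_rate = 1e-3,
                      timesteps = 1, seed = 1) {
  if (inherits(x, "pair_features")) {
    labels <- x$labels
    x <- x$x
  }
  X <- as.matrix(x)
  if (is.null(labels)) fail("training requires labels")
  y <- as.numeric(labels)
  if (length(y) != nrow(X)) fail("labels length must match rows of x")
  if (length(unique(y)) < 2L)
    fail("training requires both classes present")
  if (dropout < 0 || dropout >= 1) fail("dropout must be in [0, 1)")
  if (ncol(X) %% timesteps != 0)
    fail("feature width %d not divisible by timesteps %d", ncol(X), timesteps)
  step_w <- ncol(X) %/% timesteps

  params <- gru_init(step_w, hidden, seed = derive_seed(seed, "init"))
  history <- numeric(0)
  if (epochs > 0) {
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    N <- nrow(X)
    # tensors whose gradient can be non-zero (see gru_backward_batch)
    active <- if (timesteps == 1L)
      c("W_z", "W_h", "b_z", "b_h", "dense_w", "dense_b")
    else names(params)
    with_seed(derive_seed(seed, "train"), {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(N)
        starts <- seq(1L, N, by = batch_size)
        ep_loss <- 0
        for (s in starts) {
          idx <- ord[s:min(s + batch_size - 1L, N)]
          Xb <- X[idx, , drop = FALSE]
          yb <- y[idx]
          mask <- if (dropout > 0)
            matrix(stats::rbinom(length(idx) * hidden, 1, 1 - dropout),
                   length(idx), hidden) else NULL
          fw <- gru_forward_batch(params, Xb, timesteps, dropout, mask,
                                  keep_cache = TRUE)
          ep_loss <- ep_loss + bce_loss(fw$prob, yb) * length(idx)
          gr <- gru_backward_batch(params, Xb, yb, fw, timesteps, dropout, mask)
          step <- step + 1L
          c1 <- 1 - b1^step; c2 <- 1 - b2^step
          for (nm in active) {
            adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr[[nm]]
            adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr[[nm]]^2
            params[[nm]] <- params[[nm]] - learning_rate *
              (adam_m[[nm]] / c1) / (sqrt(adam_v[[nm]] / c2) + eps)
          }
        }
        history[ep] <- ep_loss / N
      }
    })
  }
  structure(
    list(params = params, history = history,
         config = list(hidden = hidden, dropout = dropout, epochs = epochs,
                       batch_size = batch_size, learning_rate = learning_rate,
                       timesteps = timesteps, seed = seed,
                       input_width = ncol(X))),
    class = "gru_fit"
  )
}

#' @export
print.gru_fit <- function(x, ...) {
  cat(sprintf("GRU classifier: %d hidden units, input width %d (%d timestep%s)\n",
              x$config$hidden, x$config$input_width, x$config$timesteps,
              if (x$config$timesteps == 1) "" else "s"))
  if (length(x$history))
    cat(sprintf("trained %d epochs, final mean loss %.4f\n",
                length(x$history), x$history[length(x$history)]))
  else cat("untrained (initialization only)\n")
  invisible(x)
}

#' Predict probabilities from a trained GRU
#'
#' @param object a `gru_fit` from [gru_train()].
#' @param x feature matrix or `pair_features`; width must match training.
#' @param ... unused.
#' @return A probability per row, in (0, 1); dropout is disabled.
#' @export
predict.gru_fit <- function(object, x, ...) {
  if (inherits(x, "pair_features")) x <- x$x
  X <- as.matrix(x)
  if (ncol(X) != object$config$input_width)
    fail("feature width %d does not match training width %d",
         ncol(X), object$config$input_width)
  drop(gru_forward_batch(object$params, X, object$config$timesteps)$prob)
}
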