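# Internal helpers shared across the package.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package functions do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out deterministically to independent per-stage seeds so
#' pipeline stages can be re-run in isolation. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. "negatives", "folds", "train").
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483587)
}

# stop() with a call-free, sprintf-style message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
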