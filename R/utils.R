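# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw their randomness from one master seed through
#' this map, so each stage is independently reproducible: stage `stream` of
#' master seed `s` always sees the same RNG state, and distinct streams are
#' decoupled. The map is a fixed affine hash reduced modulo 2^31 - 1 so the
#' result is always a valid 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param stream Small non-negative integer identifying the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # all arithmetic in doubles (exact below 2^53), reduced mod 2^31 - 1
  x <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + stream * 7919
  as.integer(x %% 2147483646) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored on exit.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Column-standardize a genotype (count) matrix: missing entries are replaced
# by the column mean, then each column is centred and scaled to unit variance.
# Monomorphic columns (zero variance) are returned as all-zero and reported in
# the "zero_var" attribute.
standardize_genotypes <- function(counts) {
  n <- nrow(counts)
  mu <- colMeans(counts, na.rm = TRUE)
  X <- counts
  if (anyNA(X)) {
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2L]]
  }
  X <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(X^2) / (n - 1L))
  zero <- s < .Machine$double.eps^0.5
  s[zero] <- 1
  X <- sweep(X, 2L, s, "/")
  X[, zero] <- 0
  attr(X, "zero_var") <- which(zero)
  X
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
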