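#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-unit seeds (one per
#' subject, replicate, ...) via a multiplicative congruential mix. Child
#' seeds are 31-bit non-negative integers; the scheme is a pure function of
#' \code{(seed, counter)}, so cohorts can be extended without disturbing
#' units generated earlier.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer index of the derived stream.
#' @return an integer seed in \code{[0, 2^31 - 1)}.
#' @export
derive_seed <- function(seed, counter = 0L) {
  # doubles are exact below 2^53; all intermediates stay below that
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (c in c(as.numeric(counter), 12345)) {
    s <- (s * 48271 + c * 16807 + 1) %% m
  }
  as.integer(s)
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# upper triangle of a symmetric matrix in fixed row-major pair order
# (1,2), (1,3), ..., (1,n), (2,3), ...
upper_tri_vec <- function(m) {
  t(m)[lower.tri(m)]
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot z-score a constant vector", call. = FALSE)
  (x - mean(x)) / s
}
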