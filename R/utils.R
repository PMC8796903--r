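# Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Seeds the generator for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded operations do not perturb the global
#' random stream. `seed = NULL` leaves the stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Standard error of the mean; singleton groups get 0 by convention so summary
# tables stay total (the caller decides whether to warn).
se_mean <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  stats::sd(x) / sqrt(n)
}

# 2x2 symmetric inverse, vectorised over an array slice stack.
inv2 <- function(m) {
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  matrix(c(m[2, 2], -m[2, 1], -m[1, 2], m[1, 1]), 2, 2) / d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
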