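# Internal helpers shared across modules.

#' Conversion constant: one acre in square kilometres
#'
#' Fixed at 1 acre = 0.0040468564 km^2; this constant reproduces the paired
#' acre/km^2 figures used throughout the valuation layer at 1-dp rounding.
#' @keywords internal
ACRE_KM2 <- 0.0040468564

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not perturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fan a master seed out into k independent child seeds (kept < 2^31).
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(2147483646L, k))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stopifnot with a readable message
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# sample() without its length-1 surprise
sample_safe <- function(x, size, prob = NULL) {
  if (length(x) == 0L || size == 0L) return(x[0])
  x[sample.int(length(x), size = size, prob = prob)]
}

# Euclidean distance from each row of `a` (n x 2) to nearest row of `b` (m x 2)
nearest_dist <- function(a, b) {
  if (is.null(nrow(b)) || nrow(b) == 0L) return(rep(Inf, nrow(a)))
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    out[i] <- sqrt(min((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2))
  }
  out
}

# Sample skewness (biased, moment definition)
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}
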