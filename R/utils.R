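#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically fans a single global seed out to per-stage seeds so that
#' independent pipeline stages draw from non-overlapping streams.  Results
#' stay within the 32-bit signed-integer range accepted by [set.seed()].
#'
#' @param seed master seed (integer).
#' @param k stage index (non-negative integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  as.integer((abs(seed) + 7919 * (k + 1)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level, default 0.95.
#' @return named numeric vector with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
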