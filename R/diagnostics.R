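# MCMC convergence diagnostics: split-chain potential scale reduction
# and a multi-chain effective sample size based on the initial positive
# sequence of autocorrelations.

#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is split in half and the classical between/within-variance
#' ratio is computed over the split halves, so within-chain trends inflate
#' Rhat even when full chains happen to agree.
#'
#' @param draws Matrix of posterior draws, iterations by chains.
#' @return Rhat (>= 1 up to Monte-Carlo noise; `NA` for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  w <- mean(apply(sp, 2, var))
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- half * var(colMeans(sp))
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective size of one chain from the initial positive sequence of
# sample autocorrelations (Geyer-style truncation at the first negative
# paired sum, simplified to the first negative term).
ess_one <- function(x) {
  n <- length(x)
  v <- var(x)
  if (!is.finite(v) || v == 0) return(NA_real_)
  x <- x - mean(x)
  lag_max <- min(n - 1L, 10L * floor(sqrt(n)))
  rho <- numeric(lag_max)
  denom <- sum(x^2)
  s <- 0
  for (k in seq_len(lag_max)) {
    rho[k] <- sum(x[1:(n - k)] * x[(k + 1):n]) / denom
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}

#' Multi-chain effective sample size
#'
#' Sum of per-chain effective sizes from truncated autocorrelation sums.
#'
#' @param draws Matrix of posterior draws, iterations by chains.
#' @return Estimated effective number of independent draws.
#' @export
ess_multichain <- function(draws) {
  draws <- as.matrix(draws)
  sum(apply(draws, 2, ess_one), na.rm = TRUE)
}
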