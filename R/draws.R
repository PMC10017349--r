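#' Summarise a draw vector or draw matrix
#'
#' Reduces Monte-Carlo draws to a point estimate and a 95% uncertainty
#' interval. The interval bounds are the ranked draws at positions
#' `ceiling(0.025 * n)` and `ceiling(0.975 * n)`; with the conventional
#' 1000 draws these are the 25th and 975th ranked values.
#'
#' @param x Numeric vector of draws, or a matrix with one row (or column) of
#'   draws per unit (see `margin`).
#' @param margin For matrices, the dimension that indexes units: 1 summarises
#'   each row over its columns (default), 2 each column over its rows.
#' @return For a vector, a named numeric `c(mean, lower, upper)`. For a
#'   matrix, a data.frame with columns `mean`, `lower`, `upper`.
#' @examples
#' summarise_draws(1:1000)  # lower = 25, upper = 975
#' @export
summarise_draws <- function(x, margin = 1) {
  if (is.matrix(x)) {
    if (margin == 2) x <- t(x)
    out <- t(apply(x, 1, summarise_draws))
    out <- as.data.frame(out)
    names(out) <- c("mean", "lower", "upper")
    return(out)
  }
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty draws")
  n <- length(x)
  s <- sort(x)
  c(mean = mean(x),
    lower = s[ceiling(0.025 * n)],
    upper = s[ceiling(0.975 * n)])
}

#' Derive a reproducible stage-specific seed from a run seed
#'
#' Each pipeline stage draws random numbers from its own substream so that a
#' stage can be re-run in isolation and still reproduce the full-run result.
#' The substream seed is a deterministic hash of the run seed and the stage
#' name, kept within the 32-bit integer range.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 65536 * 30011 + h * 104729 + 17) %% 2147483629)
}

#' Generate sorted draws from a (mean, 95% UI) triple via a beta distribution
#'
#' Published health-state disability weights come as a mean with a 95%
#' uncertainty interval rather than as raw draws. Draws are reconstructed
#' from a beta distribution matched by moments: the mean is matched exactly
#' and the standard deviation is taken as (upper - lower) / (2 * 1.96).
#' Draws are returned sorted ascending, so that paired health states keep
#' their severity ordering draw-wise.
#'
#' @param mean,lower,upper Point estimate and 95% UI bounds, all in (0, 1).
#' @param n_draws Number of draws.
#' @return Sorted numeric vector of length `n_draws`.
#' @export
beta_draws_from_ui <- function(mean, lower, upper, n_draws) {
  stopifnot(mean > 0, mean < 1, lower <= mean, mean <= upper)
  s <- (upper - lower) / (2 * stats::qnorm(0.975))
  if (s <= 0) return(rep(mean, n_draws))
  v <- s^2
  k <- mean * (1 - mean) / v - 1
  if (k <= 0) stop("UI too wide for a beta distribution with this mean")
  sort(stats::rbeta(n_draws, mean * k, (1 - mean) * k))
}

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
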