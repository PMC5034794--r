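#' One-sided binomial confidence bound for a population proportion
#'
#' Given k affected studies out of n examined, bounds the population
#' fraction of affected studies by inverting the binomial quantile function
#' over a grid of candidate proportions p. The lower bound is the largest
#' grid p for which observing at most k successes is still within the
#' level-plausible range (\code{qbinom(level, n, p) <= k}); the upper bound
#' is the largest grid p with \code{qbinom(1 - level, n, p) <= k}. These
#' grid searches coincide (to one grid step) with the beta-quantile
#' inversions \code{qbeta(1 - level, k + 1, n - k)} and
#' \code{qbeta(level, k + 1, n - k)}, the Clopper-Pearson-style closed
#' form. The lower bound is additionally capped at the point estimate k/n
#' (relevant only at very small k and n).
#'
#' The default grid step of 0.01 matches the whole-percent resolution at
#' which such prevalence bounds are reported.
#'
#' @param k Number of affected studies (0 <= k <= n).
#' @param n Total number of studies.
#' @param level One-sided confidence level, in (0.5, 1).
#' @param side \code{"lower"} or \code{"upper"}.
#' @param step Grid resolution over p (default 0.01).
#' @return The bound, a proportion on the grid.
#' @examples
#' binomial_bound(32, 70, level = 0.99, side = "lower")  # 0.33
#' binomial_bound(32, 70, level = 0.95, side = "upper")  # 0.56
#' @export
binomial_bound <- function(k, n, level = 0.95, side = c("lower", "upper"),
                           step = 0.01) {
  side <- match.arg(side)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || k < 0 || n < 1 || k > n) {
    stop("need integer counts with 0 <= k <= n")
  }
  if (!is.numeric(level) || level <= 0.5 || level >= 1) {
    stop("confidence level must be in (0.5, 1)")
  }
  grid <- seq(0, 1, by = step)
  q <- if (side == "lower") level else 1 - level
  ok <- grid[stats::qbinom(q, n, grid) <= k]
  bound <- if (length(ok)) max(ok) else 0
  if (side == "lower") bound <- min(bound, k / n)
  bound
}

#' Prevalence estimate with two one-sided bounds
#'
#' @param k Number of affected studies.
#' @param n Total number of studies.
#' @param level One-sided confidence level (default 0.95).
#' @param step Grid resolution passed to \code{\link{binomial_bound}}.
#' @return A \code{prevalence_estimate}: list with \code{k}, \code{n},
#'   \code{estimate} (k/n), \code{level}, \code{lower}, \code{upper}.
#' @export
prevalence_estimate <- function(k, n, level = 0.95, step = 0.01) {
  structure(list(
    k = k, n = n, estimate = k / n, level = level,
    lower = binomial_bound(k, n, level, "lower", step),
    upper = binomial_bound(k, n, level, "upper", step)
  ), class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf(
    "Affected studies: %d/%d (%.0f%%); %.0f%%-confidence one-sided bounds: lower %.0f%%, upper %.0f%%\n",
    x$k, x$n, 100 * x$estimate, 100 * x$level, 100 * x$lower, 100 * x$upper))
  invisible(x)
}
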