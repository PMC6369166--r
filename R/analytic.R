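#' Closed-form power factor of the bivariate joint test
#'
#' Under the simplifications `d = 2`, per-pair phenotypic covariance
#' `[[1, r], [r, 1]]`, relationship matrix `I`, and a second-variate effect
#' equal to `a2` times the first, the numerator of the multivariate F value
#' factorizes as `B1^2 * x'x * f(a2, r)` with
#' `f(a2, r) = (a2^2 - 2*a2*r + 1) / (1 - r^2)`.  Values above 1 indicate a
#' numerator advantage of the joint test over the univariate test on the
#' first variate; the minimum over `a2` at fixed `r` is `f(r, r) = 1`.
#'
#' @param a2 relative effect in `[-1, 1]` (vectorized).
#' @param r phenotypic correlation with `|r| < 1` (vectorized).
#' @return `f(a2, r)`.
#' @export
#' @examples
#' f_a2_r(0, 0)      # 1
#' f_a2_r(-0.8, 0.8) # strong advantage of the joint test
f_a2_r <- function(a2, r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 (division by 1 - r^2)")
  if (any(abs(a2) > 1)) stop("a2 must lie in [-1, 1]")
  (a2^2 - 2 * a2 * r + 1) / (1 - r^2)
}

#' Evaluate the power factor on a grid
#'
#' @param a2_grid,r_grid numeric vectors.
#' @return a data frame (`a2`, `r`, `f`) of class `PowerSurface` covering
#'   the full grid.
#' @export
power_surface <- function(a2_grid, r_grid) {
  gr <- expand.grid(a2 = a2_grid, r = r_grid, KEEP.OUT.ATTRS = FALSE)
  gr$f <- f_a2_r(gr$a2, gr$r)
  class(gr) <- c("PowerSurface", "data.frame")
  gr
}

# Signed relative-effect ratio of a pair: smaller magnitude over larger
# magnitude, carrying the sign of the product; ties in magnitude give +/-1.
ad_ratio <- function(b1, b2) {
  hi <- pmax(abs(b1), abs(b2))
  lo <- pmin(abs(b1), abs(b2))
  sgn <- ifelse(sign(b1) * sign(b2) >= 0, 1, -1)
  out <- ifelse(hi == 0, 1, sgn * lo / hi)
  out
}

#' Distribution of the relative-effect ratio for correlated effect pairs
#'
#' Draws `n_draws` pairs from a bivariate standard normal with correlation
#' `r` and reports, for each threshold, the fraction of pairs whose signed
#' relative-effect ratio `a_d` (smaller-magnitude element over
#' larger-magnitude element, sign retained, so `a_d` lies in `[-1, 1]`)
#' falls below it.  Quantifies how heterogeneous effect pairs drawn from a
#' strongly correlated distribution still are; the threshold-0 case has the
#' closed form [ad_sign_prob()].
#'
#' @param r correlation, `|r| < 1`.
#' @param thresholds numeric vector of thresholds in `[-1, 1]`.
#' @param n_draws Monte-Carlo sample size (>= 1e4).
#' @param seed integer seed.
#' @return named numeric vector of fractions, one per threshold.
#' @export
ad_fraction <- function(r, thresholds, n_draws = 1e6, seed = 1L) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n_draws < 1e4) stop("use at least 1e4 draws")
  set.seed(seed)
  b1 <- stats::rnorm(n_draws)
  b2 <- r * b1 + sqrt(1 - r^2) * stats::rnorm(n_draws)
  ad <- ad_ratio(b1, b2)
  out <- vapply(thresholds, function(t) mean(ad < t), 0)
  names(out) <- as.character(thresholds)
  out
}

#' Probability that a correlated effect pair has opposite signs
#'
#' Closed-form orthant probability `1/2 - asin(r)/pi` for a bivariate
#' standard normal pair; this equals the probability that the signed
#' relative-effect ratio is negative, and serves as the analytic oracle for
#' [ad_fraction()] at threshold 0.
#'
#' @param r correlation, `|r| < 1`.
#' @return the probability.
#' @export
ad_sign_prob <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  0.5 - asin(r) / pi
}
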