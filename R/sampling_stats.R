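# Binomial detection power for off-type sampling and Bayesian estimation of
# the population off-type proportion from sample counts.

#' Probability of detecting at least one off-type
#'
#' For a sample of `n` individuals drawn from a population with off-type
#' proportion `p`, and markers assumed to detect every off-type sampled,
#' the detection probability is `P = 1 - (1 - p)^n`. Computed in the
#' log1p/expm1 form for stability at small `p`.
#'
#' @param n Sample size(s), non-negative integers.
#' @param p Off-type proportion(s) in \[0, 1\].
#' @return Detection probability in \[0, 1\], vectorised over `n` and `p`.
#' @export
detection_probability <- function(n, p) {
  if (any(n < 0) || any(n != floor(n))) stop("n must be a non-negative integer")
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  len <- max(length(n), length(p))
  n <- rep_len(n, len)
  p <- rep_len(p, len)
  out <- -expm1(n * log1p(-p))
  out[p == 1] <- as.numeric(n[p == 1] >= 1)
  out
}

#' Smallest sample size reaching a target detection probability
#'
#' Inverts the detection formula: the least integer `n` with
#' `1 - (1 - p)^n >= target`, i.e. `ceiling(log(1 - target)/log(1 - p))`,
#' verified by direct evaluation at `n` and `n - 1`.
#'
#' @param p Off-type proportion, strictly inside (0, 1).
#' @param target Required detection probability, strictly inside (0, 1).
#' @return Minimal integer sample size.
#' @export
required_sample_size <- function(p, target) {
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  if (target <= 0 || target >= 1) stop("target must lie strictly in (0, 1)")
  n <- ceiling(log1p(-target) / log1p(-p))
  # guard against floating-point edge at the boundary
  while (detection_probability(n, p) < target) n <- n + 1
  while (n > 1 && detection_probability(n - 1, p) >= target) n <- n - 1
  as.integer(n)
}

#' Bayesian upper limit on the population off-type proportion
#'
#' Observing `k` off-types among `n` sampled individuals, with a
#' Beta(a, b) prior on the off-type proportion, the posterior is
#' Beta(k + a, n - k + b); the reported upper limit is its `credibility`
#' quantile (a one-sided bound, not an HPD interval). The default Jeffreys
#' prior (0.5, 0.5) is the convention of standard binomial-estimation
#' software; pass `prior = c(1, 1)` for the uniform alternative.
#'
#' @param k Off-types observed, `0 <= k <= n`.
#' @param n Sample size.
#' @param credibility Posterior quantile level in (0, 1), default 0.95.
#' @param prior Length-2 positive numeric, Beta prior parameters.
#' @return The posterior quantile, in \[0, 1\].
#' @export
bayes_upper_limit <- function(k, n, credibility = 0.95, prior = c(0.5, 0.5)) {
  if (any(k < 0) || any(k > n) || any(n < 0)) stop("need 0 <= k <= n")
  if (any(prior <= 0)) stop("prior parameters must be positive")
  if (credibility <= 0 || credibility >= 1)
    stop("credibility must lie strictly in (0, 1)")
  stats::qbeta(credibility, k + prior[1], n - k + prior[2])
}

#' Detection-probability table over sample-size and off-type grids
#'
#' @param n_grid Vector of sample sizes (rows).
#' @param p_grid Vector of off-type proportions (columns).
#' @return Matrix of `detection_probability(n, p)`, dimnames from the
#'   grids; monotone non-decreasing along both axes.
#' @export
detection_table <- function(n_grid = c(48, 96, 192, 384),
                            p_grid = c(0.001, 0.01, 0.02, 0.05, 0.1)) {
  if (length(n_grid) == 0 || length(p_grid) == 0) stop("grids must be non-empty")
  out <- outer(n_grid, p_grid, detection_probability)
  dimnames(out) <- list(n = as.character(n_grid), p = as.character(p_grid))
  out
}
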