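# Shared fixtures and independent oracles used across the suite.

# Point estimates and printed 95% CIs of the two study strains.
wt_params <- function() gompertz_params(mu0 = 0.00014, gamma = 0.0049)
k14_params <- function() gompertz_params(mu0 = 0.00013, gamma = 0.0077)

wt_table_fit <- function() {
  fit_result(0.00014, 0.0049, ci_mu0 = c(0.00011, 0.00016),
             ci_gamma = c(0.0046, 0.0052), method = "user", n_used = 69L)
}
k14_table_fit <- function() {
  fit_result(0.00013, 0.0077, ci_mu0 = c(0.00009, 0.00017),
             ci_gamma = c(0.0069, 0.0084), method = "user", n_used = 46L)
}

# Independent bisection oracle for the age at which survivorship reaches 1-p.
quantile_bisect <- function(params, p, tol = 1e-9) {
  f <- function(t) gompertz_survivorship(params, t) - (1 - p)
  lo <- 0; hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Independent two-sided Fisher p-value by full enumeration of all 2x2 tables
# with the observed margins, summing hypergeometric probabilities no larger
# than the observed table's.
fisher_enumerate <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# OLS slope/intercept/correlation from sums only (independent of lm()).
ols_by_hand <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = sxy / sqrt(sxx * syy))
}
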