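# Closed-form mathematics of the Gompertz mortality law:
# hazard mu(t) = mu0 * exp(gamma * t)
# survivorship S(t) = exp(-(mu0/gamma) * (exp(gamma*t) - 1))

#' Gompertz mortality-law parameters
#'
#' Bundle the two parameters of the Gompertz model: the initial mortality
#' `mu0` (the hazard extrapolated to age zero, an inverse proxy for initial
#' viability) and the rate of aging `gamma` (the exponential slope of the
#' hazard with age). Both are rates per day and must be strictly positive.
#'
#' @param mu0 Initial mortality, per day (> 0).
#' @param gamma Rate of aging, per day (> 0).
#' @return An object of class `gompertz_params`.
#' @examples
#' wt <- gompertz_params(mu0 = 0.00014, gamma = 0.0049)
#' gompertz_hazard(wt, 0)
#' @export
gompertz_params <- function(mu0, gamma) {
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0) ||
      !is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma)) {
    stop("'mu0' and 'gamma' must be single finite numbers", call. = FALSE)
  }
  if (mu0 <= 0 || gamma <= 0) {
    stop("Gompertz parameters must be strictly positive (got mu0 = ", mu0,
         ", gamma = ", gamma, ")", call. = FALSE)
  }
  structure(list(mu0 = as.numeric(mu0), gamma = as.numeric(gamma)),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat("Gompertz parameters: mu0 =", format(x$mu0, digits = 4),
      "/day, gamma =", format(x$gamma, digits = 4), "/day\n")
  cat("  mortality-rate doubling time:", format(log(2) / x$gamma, digits = 4),
      "days\n")
  invisible(x)
}

as_gompertz_params <- function(x) {
  if (inherits(x, "gompertz_params")) return(x)
  if (is.list(x) && all(c("mu0", "gamma") %in% names(x))) {
    return(gompertz_params(x$mu0, x$gamma))
  }
  if (is.numeric(x) && length(x) == 2L) return(gompertz_params(x[1L], x[2L]))
  stop("cannot interpret 'params' as Gompertz parameters", call. = FALSE)
}

check_age <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("ages 't' must be finite and non-negative", call. = FALSE)
  }
  t
}

#' Gompertz hazard (force of mortality)
#'
#' The instantaneous per-capita death rate at age `t`:
#' `mu(t) = mu0 * exp(gamma * t)`. Strictly increasing in age.
#'
#' @param params A [gompertz_params()] object.
#' @param t Age(s) in days (>= 0); vectorized.
#' @return Force of mortality per day.
#' @export
gompertz_hazard <- function(params, t) {
  params <- as_gompertz_params(params)
  check_age(t)
  params$mu0 * exp(params$gamma * t)
}

#' Gompertz survivorship
#'
#' Fraction of a cohort still alive at age `t`:
#' `S(t) = exp(-(mu0/gamma) * (exp(gamma*t) - 1))`.
#' Equals 1 at `t = 0`, decreases monotonically to 0.
#'
#' @inheritParams gompertz_hazard
#' @return Surviving fraction in `[0, 1]`; vectorized over `t`.
#' @export
gompertz_survivorship <- function(params, t) {
  params <- as_gompertz_params(params)
  check_age(t)
  exp(-(params$mu0 / params$gamma) * expm1(params$gamma * t))
}

#' Gompertz quantile (inverse cumulative death probability)
#'
#' Closed-form inverse of the survivorship: the age by which a fraction `p`
#' of the cohort has died, `(1/gamma) * log(1 - (gamma/mu0) * log(1 - p))`.
#'
#' @inheritParams gompertz_hazard
#' @param p Cumulative death probability, strictly inside (0, 1); vectorized.
#' @return Age in days.
#' @export
gompertz_quantile <- function(params, p) {
  params <- as_gompertz_params(params)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  # log1p(-p) = log(1 - p) without cancellation for small p
  log1p(-(params$gamma / params$mu0) * log1p(-p)) / params$gamma
}

#' Mean lifespan under a Gompertz law
#'
#' Expected age at death, the integral of the survivorship over all ages.
#' Computed by adaptive quadrature up to the 1 - 1e-12 quantile plus a closed
#' upper bound on the remaining tail (the tail integral of the survivorship is
#' at most S(T)/mu(T) because the hazard is increasing). The closed form
#' `(1/gamma) * exp(mu0/gamma) * E1(mu0/gamma)`, with E1 the exponential
#' integral, is available for cross-checking.
#'
#' @inheritParams gompertz_hazard
#' @param method `"quadrature"` (default) or `"closed-form"`.
#' @return Mean lifespan in days.
#' @export
gompertz_mean_lifespan <- function(params, method = c("quadrature", "closed-form")) {
  params <- as_gompertz_params(params)
  method <- match.arg(method)
  if (method == "closed-form") {
    x <- params$mu0 / params$gamma
    return(exp(x) * pracma::expint_E1(x) / params$gamma)
  }
  upper <- gompertz_quantile(params, 1 - 1e-12)
  body <- stats::integrate(function(t) gompertz_survivorship(params, t),
                           lower = 0, upper = upper, rel.tol = 1e-8,
                           subdivisions = 500L)$value
  tail <- gompertz_survivorship(params, upper) / gompertz_hazard(params, upper)
  body + tail
}

#' Sample lifespans from a Gompertz law
#'
#' Seeded inverse-CDF sampling: `n` independent uniform draws are pushed
#' through [gompertz_quantile()]. The random stream is scoped to the call
#' (Mersenne-Twister via [withr::with_seed()]), so global RNG state is never
#' touched and the same `(params, n, seed)` always reproduces the identical
#' sample.
#'
#' @inheritParams gompertz_hazard
#' @param n Number of lifespans (>= 1).
#' @param seed Integer seed.
#' @return An object of class `lifespan_sample` with fields `lifespans`
#'   (ages at death in days), `seed` and `params`.
#' @export
sample_lifespans <- function(params, n, seed) {
  params <- as_gompertz_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  u <- withr::with_seed(as.integer(seed), stats::runif(n))
  structure(list(lifespans = gompertz_quantile(params, u),
                 seed = as.integer(seed), params = params),
            class = "lifespan_sample")
}

#' @export
print.lifespan_sample <- function(x, ...) {
  cat("Seeded Gompertz lifespan sample: n =", length(x$lifespans),
      ", seed =", x$seed, "\n")
  cat("  mean", format(mean(x$lifespans), digits = 4), "days, range [",
      format(min(x$lifespans), digits = 4), ",",
      format(max(x$lifespans), digits = 4), "]\n")
  invisible(x)
}
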