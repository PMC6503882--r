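# Gompertz parameter estimation.
#
# Maximum likelihood on per-animal lifespans with right censoring, and
# nonlinear least squares on survival-curve point tables. Both work on the
# transformed scale (a, g) = (ln mu0, gamma) so that positivity of mu0 is
# structural and the optimization is well conditioned (mu0 spans orders of
# magnitude). gamma is box-constrained to (1e-6, 1) per day.

GAMMA_LOWER <- 1e-6
GAMMA_UPPER <- 1

# Log-likelihood and its analytic derivatives on the (a = ln mu0, g) scale.
# Deaths contribute a + g*t - (e^a/g)(e^{g t}-1); censored animals only the
# cumulative-hazard term.
gomp_ll_parts <- function(a, g, t, d) {
  egt <- exp(g * t)
  S0 <- sum(expm1(g * t))        # sum over all animals
  S1 <- sum(t * egt)
  S2 <- sum(t * t * egt)
  nd <- sum(d)
  mu0 <- exp(a)
  ll <- nd * a + g * sum(t[d == 1L]) - (mu0 / g) * S0
  grad <- c(nd - (mu0 / g) * S0,
            sum(t[d == 1L]) - mu0 * (S1 / g - S0 / g^2))
  hess <- matrix(c(-(mu0 / g) * S0,
                   -mu0 * (S1 / g - S0 / g^2),
                   -mu0 * (S1 / g - S0 / g^2),
                   -mu0 * (S2 / g - 2 * S1 / g^2 + 2 * S0 / g^3)),
                 2L, 2L)
  list(ll = ll, grad = grad, hess = hess)
}

# Profile log-likelihood over g: the MLE of mu0 at fixed g is closed-form,
# mu0(g) = nd * g / sum(expm1(g t)).
gomp_profile_ll <- function(g, t, d) {
  nd <- sum(d)
  S0 <- sum(expm1(g * t))
  if (!is.finite(S0)) return(-.Machine$double.xmax)  # e^{g t} overflow far from optimum
  nd * log(nd * g / S0) + g * sum(t[d == 1L]) - nd
}

#' Fit the Gompertz model to per-animal lifespans by maximum likelihood
#'
#' Maximizes the censored Gompertz log-likelihood over (ln mu0, gamma). The
#' aging rate is first located by maximizing the one-dimensional profile
#' log-likelihood (mu0 has a closed-form conditional MLE), then the joint
#' optimum is polished by safeguarded Newton iterations with analytic
#' gradient and Hessian until the gradient norm is below `1e-8 * max(1,
#' deaths)`. Wald 95% confidence intervals come from the observed information
#' matrix on the (ln mu0, gamma) scale, back-transformed for mu0.
#'
#' @param x A [cohort()], a `lifespan_sample`, or a numeric vector of
#'   uncensored lifespans in days.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @param bootstrap If `TRUE`, replace the Wald intervals by seeded
#'   nonparametric bootstrap percentile intervals.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `gompertz_fit` object: `params`, `ci_mu0`, `ci_gamma`,
#'   `objective` (maximized log-likelihood), `method = "lifespan-ML"`,
#'   `n_used`, `n_events`, `vcov` (on the transformed scale).
#' @export
fit_ml <- function(x, conf_level = 0.95, bootstrap = FALSE, n_boot = 1000L,
                   boot_seed = 1L) {
  if (inherits(x, "lifespan_sample")) x <- x$lifespans
  if (is.numeric(x)) x <- cohort(x)
  stopifnot(inherits(x, "cohort"))
  t <- x$lifespan_days
  d <- x$event
  nd <- sum(d)
  if (nd == 0L) stop("all-censored cohort: no deaths to fit", call. = FALSE)
  if (nd < 5L) {
    stop("need at least 5 uncensored deaths to fit (got ", nd, ")",
         call. = FALSE)
  }

  g <- stats::optimize(gomp_profile_ll, c(GAMMA_LOWER, GAMMA_UPPER),
                       t = t, d = d, maximum = TRUE, tol = 1e-10)$maximum
  a <- log(nd * g / sum(expm1(g * t)))

  tol <- 1e-8 * max(1, nd)
  cur <- gomp_ll_parts(a, g, t, d)
  for (iter in seq_len(60L)) {
    if (max(abs(cur$grad)) <= tol) break
    step <- tryCatch(solve(cur$hess, -cur$grad),
                     error = function(e) -cur$grad / max(abs(cur$grad)))
    lam <- 1
    repeat {
      a_new <- a + lam * step[1L]
      g_new <- min(max(g + lam * step[2L], GAMMA_LOWER), GAMMA_UPPER)
      nxt <- gomp_ll_parts(a_new, g_new, t, d)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-12) break
    }
    if (lam < 1e-12) break
    a <- a_new; g <- g_new; cur <- nxt
  }
  if (max(abs(cur$grad)) > tol) {
    stop("ML fit did not converge: gradient norm ",
         format(max(abs(cur$grad)), digits = 3), " exceeds tolerance ",
         format(tol, digits = 3), " after Newton polishing (n = ",
         length(t), ", deaths = ", nd, ")", call. = FALSE)
  }

  info <- -cur$hess
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2L, 2L))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(pmax(diag(vc), 0))
  ci_mu0 <- exp(a + c(-1, 1) * z * se[1L])
  ci_gamma <- pmax(g + c(-1, 1) * z * se[2L], 1e-12)

  if (bootstrap) {
    n <- length(t)
    est <- withr::with_seed(as.integer(boot_seed), {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        fb <- tryCatch(fit_ml(cohort(t[idx], event = d[idx])),
                       error = function(e) NULL)
        if (is.null(fb)) c(NA_real_, NA_real_)
        else c(log(fb$params$mu0), fb$params$gamma)
      }, c(0, 0))
    })
    alpha <- (1 - conf_level) / 2
    ci_mu0 <- exp(stats::quantile(est[1L, ], c(alpha, 1 - alpha), na.rm = TRUE,
                                  names = FALSE))
    ci_gamma <- stats::quantile(est[2L, ], c(alpha, 1 - alpha), na.rm = TRUE,
                                names = FALSE)
  }

  fit_result(mu0 = exp(a), gamma = g, ci_mu0 = ci_mu0, ci_gamma = ci_gamma,
             objective = cur$ll, method = "lifespan-ML", n_used = length(t),
             n_events = nd, vcov = vc, conf_level = conf_level)
}

#' Fit the Gompertz model to survival-curve points by least squares
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nlsLM()]) of
#' `N0 * exp(-(mu0/gamma) * (exp(gamma*t) - 1))` to (age, survivors) points,
#' parameterized on (ln mu0, gamma). Starting values come from a linear
#' regression of the log empirical hazard (finite differences of the log
#' curve) on age. Confidence intervals use the linearized covariance at the
#' optimum.
#'
#' @param curve A [survival_curve()].
#' @param weights `"none"` (default) or `"binomial"` — inverse-variance
#'   weights `N0 / (N(t) * (N0 - N(t)))` from the binomial variance of the
#'   survivor counts (points with zero variance get the largest finite
#'   weight present).
#' @param conf_level Confidence level (default 0.95).
#' @param start Optional named list `list(a = , g = )` of starting values on
#'   the (ln mu0, gamma) scale, overriding the hazard-regression init.
#' @return A `gompertz_fit` with `method = "curve-LS"` and `objective` the
#'   residual sum of squares.
#' @export
fit_curve <- function(curve, weights = c("none", "binomial"),
                      conf_level = 0.95, start = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  weights <- match.arg(weights)
  age <- curve$age_days
  surv <- curve$survivors
  n0 <- curve$n0
  if (length(age) < 5L) {
    stop("need at least 5 curve points to fit", call. = FALSE)
  }
  pos <- surv[surv > 0]
  if (length(unique(surv)) < 3L) {
    stop("degenerate survival curve (flat or single-step)", call. = FALSE)
  }
  if (max(pos) / min(pos) < 2) {
    stop("curve must span at least a 2-fold drop in survivors", call. = FALSE)
  }

  # init: empirical hazard from log-curve differences, log-linear in age
  keep <- which(surv > 0)
  ls <- log(surv[keep])
  mid <- (age[keep][-1] + age[keep][-length(keep)]) / 2
  h <- -diff(ls) / diff(age[keep])
  ok <- is.finite(h) & h > 0
  if (sum(ok) >= 2L) {
    co <- stats::coef(stats::lm(log(h[ok]) ~ mid[ok]))
    g0 <- min(max(co[2L], 1e-5), 0.5)
    a0 <- min(max(co[1L], -25), -1)
  } else {
    g0 <- 0.005; a0 <- -9
  }
  if (!is.null(start)) {
    a0 <- start$a
    g0 <- start$g
  }

  w <- rep(1, length(age))
  if (weights == "binomial") {
    v <- surv * (n0 - surv) / n0
    w <- 1 / v
    w[!is.finite(w) | v <= 0] <- NA
    w[is.na(w)] <- max(w, na.rm = TRUE)
  }

  df <- data.frame(age = age, surv = surv)
  fit <- minpack.lm::nlsLM(
    surv ~ n0 * exp(-(exp(a) / g) * expm1(g * age)),
    data = df, start = list(a = a0, g = g0),
    lower = c(-30, GAMMA_LOWER), upper = c(0, GAMMA_UPPER),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2L, 2L))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(pmax(diag(vc), 0))
  ci_mu0 <- exp(est[["a"]] + c(-1, 1) * z * se[1L])
  ci_gamma <- pmax(est[["g"]] + c(-1, 1) * z * se[2L], 1e-12)

  fit_result(mu0 = exp(est[["a"]]), gamma = est[["g"]],
             ci_mu0 = ci_mu0, ci_gamma = ci_gamma,
             objective = stats::deviance(fit), method = "curve-LS",
             n_used = length(age), n_events = NA_integer_, vcov = vc,
             conf_level = conf_level)
}

#' Assemble a Gompertz fit result
#'
#' Constructor for fit results, also usable directly for published estimates
#' (point values with their printed 95% confidence intervals), which can then
#' be compared or classified like fits produced in-package.
#'
#' @param mu0,gamma Point estimates (per day).
#' @param ci_mu0,ci_gamma Length-2 confidence bounds bracketing the estimates;
#'   all bounds positive.
#' @param objective Log-likelihood (ML) or residual sum of squares (LS).
#' @param method Fit provenance, e.g. `"lifespan-ML"`, `"curve-LS"`, `"user"`.
#' @param n_used Number of observations used.
#' @param n_events Number of deaths (ML fits).
#' @param vcov Optional 2x2 covariance on the (ln mu0, gamma) scale.
#' @param conf_level Confidence level of the intervals.
#' @return An object of class `gompertz_fit`.
#' @export
fit_result <- function(mu0, gamma, ci_mu0, ci_gamma, objective = NA_real_,
                       method = "user", n_used = NA_integer_,
                       n_events = NA_integer_, vcov = NULL,
                       conf_level = 0.95) {
  params <- gompertz_params(mu0, gamma)
  ci_mu0 <- as.numeric(ci_mu0)
  ci_gamma <- as.numeric(ci_gamma)
  check_ci <- function(ci, est, what) {
    if (length(ci) != 2L || any(!is.finite(ci)) || any(ci <= 0) ||
        ci[1L] > ci[2L] || est < ci[1L] || est > ci[2L]) {
      stop("invalid ", what, " confidence interval: must be positive bounds ",
           "bracketing the estimate", call. = FALSE)
    }
  }
  check_ci(ci_mu0, mu0, "mu0")
  check_ci(ci_gamma, gamma, "gamma")
  structure(list(params = params, ci_mu0 = ci_mu0, ci_gamma = ci_gamma,
                 objective = objective, method = method,
                 n_used = n_used, n_events = n_events, vcov = vcov,
                 conf_level = conf_level),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  lev <- format(100 * x$conf_level)
  cat("Gompertz fit (", x$method, ", n = ", x$n_used, ")\n", sep = "")
  cat(sprintf("  mu0   = %.3g /day  (%s%% CI %.3g - %.3g)\n",
              x$params$mu0, lev, x$ci_mu0[1L], x$ci_mu0[2L]))
  cat(sprintf("  gamma = %.3g /day  (%s%% CI %.3g - %.3g)\n",
              x$params$gamma, lev, x$ci_gamma[1L], x$ci_gamma[2L]))
  if (is.finite(x$objective)) {
    lbl <- if (identical(x$method, "curve-LS")) "SSE" else "logLik"
    cat("  ", lbl, " = ", format(x$objective, digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' Compare two fits by confidence-interval overlap
#'
#' Two parameter estimates are called significantly different when their
#' confidence intervals are disjoint — the comparison rule used for the
#' Gompertz parameters throughout the package.
#'
#' @param a,b `gompertz_fit` objects.
#' @param which `"gamma"` or `"mu0"`.
#' @return `"disjoint"` or `"overlapping"`.
#' @export
ci_overlap <- function(a, b, which = c("gamma", "mu0")) {
  which <- match.arg(which)
  stopifnot(inherits(a, "gompertz_fit"), inherits(b, "gompertz_fit"))
  ci_a <- if (which == "gamma") a$ci_gamma else a$ci_mu0
  ci_b <- if (which == "gamma") b$ci_gamma else b$ci_mu0
  if (ci_a[2L] < ci_b[1L] || ci_b[2L] < ci_a[1L]) "disjoint" else "overlapping"
}
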