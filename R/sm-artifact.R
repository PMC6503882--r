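# Strehler-Mildvan artifact machinery.
#
# Estimation errors of the two Gompertz parameters are negatively coupled:
# refitting subsamples of one homogeneous population scatters the estimates
# along a line of negative slope in the (gamma, ln mu0) plane even though the
# underlying law never changed. That artifactual regression is the reference
# against which an observed parameter-change vector must be judged before a
# lifespan difference is attributed to the rate of aging or to the initial
# mortality.

#' Strehler-Mildvan reference regression
#'
#' Constructor for the reference regression of `ln mu0` on `gamma`. Usually
#' produced by [build_reference_by_subsampling()] or
#' [build_reference_from_fits()]; build one directly to supply a published
#' reference line (provenance `"user-supplied"`), in which case the plane
#' scales `sd_gamma` and `sd_ln_mu0` must be given for classification.
#'
#' @param slope Regression slope d(ln mu0)/d(gamma), in days.
#' @param intercept Regression intercept, ln(per day).
#' @param r Correlation of the point cloud.
#' @param points Optional data.frame with columns `gamma`, `ln_mu0`.
#' @param provenance One of `"subsampled-single-population"`,
#'   `"pooled-controls"`, `"user-supplied"`.
#' @param sd_gamma,sd_ln_mu0 Cloud standard deviations used to normalize the
#'   plane during classification; computed from `points` when available.
#' @param n_failed Number of subsample fits dropped (subsampling provenance).
#' @return An object of class `sm_reference`.
#' @export
sm_reference <- function(slope, intercept, r = NA_real_, points = NULL,
                         provenance = c("user-supplied",
                                        "subsampled-single-population",
                                        "pooled-controls"),
                         sd_gamma = NULL, sd_ln_mu0 = NULL, n_failed = 0L) {
  provenance <- match.arg(provenance)
  if (!is.finite(slope)) stop("reference slope must be finite", call. = FALSE)
  if (!is.null(points)) {
    stopifnot(is.data.frame(points), all(c("gamma", "ln_mu0") %in% names(points)))
    if (is.null(sd_gamma)) sd_gamma <- stats::sd(points$gamma)
    if (is.null(sd_ln_mu0)) sd_ln_mu0 <- stats::sd(points$ln_mu0)
  }
  if (provenance == "subsampled-single-population" && slope >= 0) {
    warning("subsampled single-population reference has non-negative slope; ",
            "this violates the defining artifact and will be refused by ",
            "classify_vector()", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r = r, points = points,
                 provenance = provenance, sd_gamma = sd_gamma,
                 sd_ln_mu0 = sd_ln_mu0, n_failed = n_failed),
            class = "sm_reference")
}

#' @export
print.sm_reference <- function(x, ...) {
  cat("Strehler-Mildvan reference regression (", x$provenance, ")\n", sep = "")
  cat(sprintf("  ln mu0 = %.4g %+.4g * gamma   (r = %.3f, %d points)\n",
              x$intercept, x$slope,
              x$r, if (is.null(x$points)) 0L else nrow(x$points)))
  invisible(x)
}

#' @export
as.data.frame.sm_reference <- function(x, ...) {
  data.frame(slope = x$slope, intercept = x$intercept, r = x$r,
             provenance = x$provenance,
             sd_gamma = if (is.null(x$sd_gamma)) NA_real_ else x$sd_gamma,
             sd_ln_mu0 = if (is.null(x$sd_ln_mu0)) NA_real_ else x$sd_ln_mu0,
             n_points = if (is.null(x$points)) 0L else nrow(x$points),
             n_failed = x$n_failed)
}

#' Build the artifactual reference by subsampling one population
#'
#' Draws `n_reps` independent cohorts of size `n_sub` from a single Gompertz
#' law, fits each by [fit_ml()], and regresses the fitted `ln mu0` on the
#' fitted `gamma` by ordinary least squares (gamma as abscissa). Because the
#' generating law is fixed, the whole regression is estimation artifact: its
#' slope is negative and the point-cloud correlation strongly so.
#'
#' @param params Generating [gompertz_params()].
#' @param n_sub Subsample size (>= 10).
#' @param n_reps Number of replicate subsamples (>= 20).
#' @param seed Integer seed; replicate seeds are drawn from it, so the whole
#'   reference is reproducible.
#' @return An [sm_reference()] with provenance
#'   `"subsampled-single-population"`.
#' @export
build_reference_by_subsampling <- function(params, n_sub, n_reps, seed) {
  params <- as_gompertz_params(params)
  if (n_sub < 10L) stop("'n_sub' must be >= 10", call. = FALSE)
  if (n_reps < 20L) stop("'n_reps' must be >= 20", call. = FALSE)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, n_reps))
  fits <- lapply(sub_seeds, function(s) {
    tryCatch(fit_ml(sample_lifespans(params, n_sub, s)),
             error = function(e) NULL)
  })
  failed <- vapply(fits, is.null, TRUE)
  if (mean(failed) > 0.2) {
    stop("more than 20% of subsample fits failed (", sum(failed), " of ",
         n_reps, ")", call. = FALSE)
  }
  fits <- fits[!failed]
  ref <- build_reference_from_fits(fits)
  ref$provenance <- "subsampled-single-population"
  ref$n_failed <- sum(failed)
  if (ref$slope >= 0) {
    warning("subsampled reference slope is non-negative", call. = FALSE)
  }
  ref
}

#' Build a reference regression from supplied fits
#'
#' Ordinary least squares of `ln mu0` on `gamma` across a set of fits, e.g.
#' the control arms of several published experiments.
#'
#' @param fits List of `gompertz_fit` objects (>= 3, not all identical).
#' @return An [sm_reference()] with provenance `"pooled-controls"`.
#' @export
build_reference_from_fits <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "gompertz_fit")))
  if (length(fits) < 3L) stop("need at least 3 fits", call. = FALSE)
  gam <- vapply(fits, function(f) f$params$gamma, 0)
  lmu <- vapply(fits, function(f) log(f$params$mu0), 0)
  if (stats::sd(gam) == 0) {
    stop("degenerate input: no variation in gamma across fits", call. = FALSE)
  }
  co <- stats::coef(stats::lm(lmu ~ gam))
  r <- if (stats::sd(lmu) == 0) 0 else stats::cor(gam, lmu)
  sm_reference(slope = unname(co[2L]), intercept = unname(co[1L]), r = r,
               points = data.frame(gamma = gam, ln_mu0 = lmu),
               provenance = "pooled-controls")
}

#' Parameter-change vector between two fits
#'
#' The displacement of a treated cohort relative to a control in the
#' (gamma, ln mu0) plane: `d_gamma = gamma_t - gamma_c`,
#' `d_ln_mu0 = ln(mu0_t) - ln(mu0_c)`, together with the CI-overlap verdicts
#' for each component and the mean CI half-widths (used as the default null
#' tolerance during classification).
#'
#' @param control,treated `gompertz_fit` objects.
#' @return An object of class `param_change`.
#' @export
change_vector <- function(control, treated) {
  stopifnot(inherits(control, "gompertz_fit"), inherits(treated, "gompertz_fit"))
  half <- function(ci) diff(ci) / 2
  half_log <- function(ci) diff(log(ci)) / 2
  structure(list(
    d_gamma = treated$params$gamma - control$params$gamma,
    d_ln_mu0 = log(treated$params$mu0) - log(control$params$mu0),
    gamma_overlap = ci_overlap(control, treated, "gamma") == "overlapping",
    mu0_overlap = ci_overlap(control, treated, "mu0") == "overlapping",
    tol_gamma = mean(c(half(control$ci_gamma), half(treated$ci_gamma))),
    tol_ln_mu0 = mean(c(half_log(control$ci_mu0), half_log(treated$ci_mu0)))),
    class = "param_change")
}

#' @export
print.param_change <- function(x, ...) {
  cat(sprintf("Parameter-change vector: d_gamma = %+.4g (CIs %s), d_ln_mu0 = %+.4g (CIs %s)\n",
              x$d_gamma, if (x$gamma_overlap) "overlap" else "disjoint",
              x$d_ln_mu0, if (x$mu0_overlap) "overlap" else "disjoint"))
  invisible(x)
}

#' Classify a parameter-change vector against the artifactual reference
#'
#' Decomposes the change vector, in a normalized (gamma, ln mu0) plane where
#' one reference-cloud standard deviation of each coordinate maps to unit
#' length, into a component along the reference direction and an orthogonal
#' residual. Shares are squared-norm fractions. Classification rules, applied
#' in order:
#'
#' 1. `null` — both CI-overlap flags are "overlap" and both raw components
#'    are below the null tolerance (default: the mean CI half-widths).
#' 2. `largely_artifactual` — the orthogonal share is below `theta`: the
#'    displacement is mostly what refitting noise alone would produce.
#' 3. `aging_rate_change` — the gamma axis carries at least `1 - theta` of
#'    the normalized vector and the mu0 CIs overlap.
#' 4. `initial_mortality_change` — symmetric in the other axis.
#' 5. `mixed_real` — otherwise.
#'
#' The continuous decomposition is always returned alongside the label.
#'
#' @param v A [change_vector()].
#' @param ref An [sm_reference()]; if its provenance is
#'   `"subsampled-single-population"` its slope must be negative (the
#'   defining artifact), otherwise classification is refused.
#' @param theta Artifactual-dominance share threshold (default 0.25).
#' @param null_tol Optional list with `gamma` and `ln_mu0` overriding the
#'   null tolerance.
#' @return An object of class `sm_classification`: `label`, normalized vector
#'   `v_norm`, `along` and `orth` components, `orth_share`, `gamma_share`,
#'   `mu0_share`, the scales and `theta` used.
#' @export
classify_vector <- function(v, ref, theta = 0.25, null_tol = NULL) {
  stopifnot(inherits(v, "param_change"), inherits(ref, "sm_reference"))
  if (theta <= 0 || theta >= 1) stop("'theta' must be in (0,1)", call. = FALSE)
  if (ref$provenance == "subsampled-single-population" && ref$slope >= 0) {
    stop("refusing reference: subsampled single-population reference must ",
         "have negative slope", call. = FALSE)
  }
  sx <- ref$sd_gamma
  sy <- ref$sd_ln_mu0
  if (is.null(sx) || is.null(sy) || !is.finite(sx) || !is.finite(sy) ||
      sx <= 0 || sy <= 0) {
    stop("reference carries no usable plane scales (sd_gamma, sd_ln_mu0); ",
         "supply them for user-supplied references", call. = FALSE)
  }
  tol_g <- if (is.null(null_tol)) v$tol_gamma else null_tol$gamma
  tol_m <- if (is.null(null_tol)) v$tol_ln_mu0 else null_tol$ln_mu0

  # unit reference direction in the normalized plane
  m <- ref$slope * sx / sy
  u <- c(1, m) / sqrt(1 + m^2)
  vn <- c(gamma = v$d_gamma / sx, ln_mu0 = v$d_ln_mu0 / sy)
  along_len <- sum(vn * u)
  along <- along_len * u
  orth <- vn - along
  tot <- sum(vn^2)

  if (tot == 0) {
    label <- "null"
    orth_share <- gamma_share <- mu0_share <- NA_real_
  } else {
    orth_share <- sum(orth^2) / tot
    gamma_share <- vn[[1L]]^2 / tot
    mu0_share <- vn[[2L]]^2 / tot
    small <- abs(v$d_gamma) <= tol_g && abs(v$d_ln_mu0) <= tol_m
    if (v$gamma_overlap && v$mu0_overlap && small) {
      label <- "null"
    } else if (orth_share < theta) {
      label <- "largely_artifactual"
    } else if (gamma_share >= 1 - theta && v$mu0_overlap) {
      label <- "aging_rate_change"
    } else if (mu0_share >= 1 - theta && v$gamma_overlap) {
      label <- "initial_mortality_change"
    } else {
      label <- "mixed_real"
    }
  }
  structure(list(label = label, v_norm = vn, along = along, orth = orth,
                 orth_share = orth_share, gamma_share = gamma_share,
                 mu0_share = mu0_share, theta = theta,
                 scales = c(sd_gamma = sx, sd_ln_mu0 = sy),
                 reference_slope = ref$slope,
                 null_tol = c(gamma = tol_g, ln_mu0 = tol_m)),
            class = "sm_classification")
}

#' @export
print.sm_classification <- function(x, ...) {
  cat("SM classification:", x$label, "\n")
  if (is.finite(x$orth_share %||% NA_real_)) {
    cat(sprintf("  orthogonal share %.3f, gamma share %.3f, mu0 share %.3f (theta = %.2f)\n",
                x$orth_share, x$gamma_share, x$mu0_share, x$theta))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.data.frame.sm_classification <- function(x, ...) {
  data.frame(label = x$label,
             v_gamma_norm = x$v_norm[[1L]], v_ln_mu0_norm = x$v_norm[[2L]],
             along_gamma = x$along[[1L]], along_ln_mu0 = x$along[[2L]],
             orth_gamma = x$orth[[1L]], orth_ln_mu0 = x$orth[[2L]],
             orth_share = x$orth_share, gamma_share = x$gamma_share,
             mu0_share = x$mu0_share, theta = x$theta,
             reference_slope = x$reference_slope)
}

#' Serialize SM reference or classification results to JSON
#'
#' @param x An `sm_reference` or `sm_classification`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
sm_to_json <- function(x, path = NULL) {
  rec <- as.list(as.data.frame(x))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Plot the (gamma, ln mu0) plane with a reference line and change vectors
#'
#' @param x An `sm_reference`.
#' @param vectors Optional list of [change_vector()]s drawn from `origin`.
#' @param origin A `gompertz_fit` giving the control point vectors start at.
#' @param ... Passed to [plot()].
#' @export
plot.sm_reference <- function(x, vectors = NULL, origin = NULL, ...) {
  pts <- x$points
  if (is.null(pts)) stop("reference has no point cloud to plot", call. = FALSE)
  plot(pts$gamma, pts$ln_mu0, pch = 16, col = "grey60",
       xlab = expression(gamma ~ "(1/day)"), ylab = expression(ln ~ mu[0]), ...)
  graphics::abline(x$intercept, x$slope, lwd = 2)
  if (!is.null(vectors) && !is.null(origin)) {
    g0 <- origin$params$gamma
    m0 <- log(origin$params$mu0)
    for (v in vectors) {
      graphics::arrows(g0, m0, g0 + v$d_gamma, m0 + v$d_ln_mu0,
                       length = 0.08, lwd = 2, col = "black")
    }
  }
  invisible(x)
}
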