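# Cohort descriptive statistics, tumor-censored Kaplan-Meier comparison,
# and the contingency / rank tests used alongside the parametric analysis.
# Kaplan-Meier and log-rank machinery comes from the survival package;
# Fisher, chi-square and Mann-Whitney from stats.

#' Cohort summary statistics
#'
#' Maximum, median and mean (+/- sample SD) lifespan, plus the mean (+/- SD)
#' of the longest-lived decile — the "last 10% survivors", a robust maximal
#' lifespan summary. Requires a fully observed cohort (no censoring): these
#' descriptive rows are undefined otherwise.
#'
#' @param x A [cohort()] with all events observed.
#' @param top_fraction Fraction defining the long-lived tail; the tail holds
#'   the `ceiling(top_fraction * N0)` longest-lived animals (default 0.1).
#' @return An object of class `cohort_summary` with fields `n0`, `max`,
#'   `median`, `mean`, `sd`, `top_n`, `top_mean`, `top_sd`.
#' @export
summarize_cohort <- function(x, top_fraction = 0.1) {
  stopifnot(inherits(x, "cohort"))
  if (any(x$event == 0L)) {
    stop("summary rows require an all-deaths cohort (no censoring)",
         call. = FALSE)
  }
  t <- x$lifespan_days
  k <- as.integer(ceiling(top_fraction * x$n0))
  top <- sort(t, decreasing = TRUE)[seq_len(k)]
  structure(list(group = x$group, n0 = x$n0,
                 max = max(t),
                 median = stats::median(t),
                 mean = mean(t), sd = stats::sd(t),
                 top_n = k, top_mean = mean(top),
                 top_sd = if (k > 1L) stats::sd(top) else NA_real_),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary '", x$group, "' (N0 = ", x$n0, ")\n", sep = "")
  cat(sprintf("  maximum lifespan: %.0f days\n", x$max))
  cat(sprintf("  median lifespan:  %.0f days\n", x$median))
  cat(sprintf("  mean lifespan:    %.0f +/- %.0f days\n", x$mean, x$sd))
  cat(sprintf("  last %d survivors: %.0f +/- %.0f days\n",
              x$top_n, x$top_mean, x$top_sd))
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(group = x$group, n0 = x$n0, max_lifespan = x$max,
             median_lifespan = x$median, mean_lifespan = x$mean,
             sd_lifespan = x$sd, top_n = x$top_n, top_mean = x$top_mean,
             top_sd = x$top_sd)
}

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Signed percent difference of a treated value relative to control
#'
#' `100 * (treated - control) / control`, rounded half away from zero to the
#' requested number of decimals.
#'
#' @param control,treated Numeric values (control non-zero); vectorized.
#' @param decimals Decimals to round to (default 0).
#' @return Signed percent difference(s).
#' @export
percent_difference <- function(control, treated, decimals = 0) {
  if (any(control == 0)) stop("control value must be non-zero", call. = FALSE)
  round_half_away(100 * (treated - control) / control, decimals)
}

censor_rules <- c("all-deaths", "tumor-bearing-only",
                  "tumor-excluding-papilloma-only")

# event indicator under a cause-specific censoring rule:
# tumor-bearing-only counts only deaths with >= 1 postmortem tumor as events;
# the papilloma-excluding rule additionally treats deaths whose only tumor
# label is papilloma as censorings.
event_under_rule <- function(x, censor_rule) {
  if (!censor_rule %in% censor_rules) {
    stop("unknown censoring rule '", censor_rule, "'; use one of: ",
         paste(censor_rules, collapse = ", "), call. = FALSE)
  }
  if (censor_rule == "all-deaths") return(x$event)
  if (!x$has_tumor_annotation) {
    stop("cohort carries no tumor annotation; tumor-based censoring rules ",
         "are unavailable", call. = FALSE)
  }
  labs <- x$tumor_labels
  if (censor_rule == "tumor-bearing-only") {
    as.integer(x$event == 1L & lengths(labs) > 0L)
  } else {
    as.integer(x$event == 1L &
                 vapply(labs, function(l) any(l != "papilloma"), TRUE))
  }
}

#' Kaplan-Meier estimate with cause-specific tumor censoring
#'
#' Product-limit estimator (via [survival::survfit()]). Under
#' `"tumor-bearing-only"` only deaths with a postmortem tumor count as
#' events — tumor-free deaths become censorings at their death age, so the
#' curve estimates the probability of not having died tumor-bearing by a
#' given age. `"tumor-excluding-papilloma-only"` additionally censors deaths
#' whose only tumor is a papilloma.
#'
#' @param x A [cohort()].
#' @param censor_rule One of `"all-deaths"`, `"tumor-bearing-only"`,
#'   `"tumor-excluding-papilloma-only"`.
#' @return An object of class `km_curve`: `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`, plus the rule and `n0`.
#' @export
km_estimate <- function(x, censor_rule = "all-deaths") {
  stopifnot(inherits(x, "cohort"))
  ev <- event_under_rule(x, censor_rule)
  sf <- survival::survfit(survival::Surv(x$lifespan_days, ev) ~ 1,
                          conf.type = "none")
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, n_censor = sf$n.censor,
                 censor_rule = censor_rule, n0 = x$n0, group = x$group),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve ('", x$group, "', rule = ", x$censor_rule,
      "): ", sum(x$n_event), " events, ", sum(x$n_censor),
      " censored of ", x$n0, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, survival = x$surv, at_risk = x$n_risk,
             events = x$n_event, censored = x$n_censor)
}

#' Two-sample log-rank test
#'
#' Standard log-rank comparison of two cohorts' event-time distributions
#' (via [survival::survdiff()]), optionally under a tumor censoring rule.
#'
#' @param a,b [cohort()]s.
#' @param censor_rule As in [km_estimate()].
#' @return List with `chisq` (1 df statistic), `p_value`, and per-group
#'   observed/expected event counts.
#' @export
logrank_test <- function(a, b, censor_rule = "all-deaths") {
  stopifnot(inherits(a, "cohort"), inherits(b, "cohort"))
  time <- c(a$lifespan_days, b$lifespan_days)
  ev <- c(event_under_rule(a, censor_rule), event_under_rule(b, censor_rule))
  if (sum(ev) == 0L) stop("no events in the pooled sample", call. = FALSE)
  grp <- factor(rep(c("a", "b"), c(a$n0, b$n0)))  # robust to equal labels
  sd <- survival::survdiff(survival::Surv(time, ev) ~ grp)
  obs <- stats::setNames(sd$obs, c(a$group, b$group))
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = obs,
       expected = stats::setNames(sd$exp, c(a$group, b$group)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing hypergeometric probabilities no larger
#' than the observed table's (the [stats::fisher.test()] convention).
#'
#' @param x A 2x2 matrix of non-negative integer counts, or a length-4 vector
#'   filled by row.
#' @return The `htest` object from [stats::fisher.test()].
#' @export
fisher_exact <- function(x) {
  if (is.numeric(x) && length(x) == 4L) x <- matrix(x, 2L, 2L, byrow = TRUE)
  if (!is.matrix(x) || !all(dim(x) == 2L) || any(x < 0) ||
      any(x != round(x))) {
    stop("'x' must be a 2x2 table of non-negative integer counts",
         call. = FALSE)
  }
  stats::fisher.test(x)
}

#' Chi-square test for a 2x2 table
#'
#' @inheritParams fisher_exact
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return The `htest` object from [stats::chisq.test()].
#' @export
chisq_2x2 <- function(x, correct = TRUE) {
  if (is.numeric(x) && length(x) == 4L) x <- matrix(x, 2L, 2L, byrow = TRUE)
  stats::chisq.test(x, correct = correct)
}

organ_variables <- c("body_weight_g", "thymus_weight_mg", "spleen_weight_mg",
                     "log2_thymulin_titer")

#' Compare organ-panel variables between groups within an age window
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per measured variable for
#' observations whose sacrifice age falls inside the window. Variables with
#' fewer than 3 observations in either group are flagged `testable = FALSE`
#' rather than silently dropped.
#'
#' @param panel_a,panel_b Organ-panel data.frames (see
#'   [read_organ_panel_csv()] for the dialect).
#' @param age_window Length-2 numeric, inclusive age window in months.
#' @param variables Variables to test (default: the four panel measurements).
#' @return A data.frame with one row per variable: `variable`, `n_a`, `n_b`,
#'   `p_value`, `testable`.
#' @export
age_interval_compare <- function(panel_a, panel_b, age_window,
                                 variables = organ_variables) {
  stopifnot(length(age_window) == 2L, age_window[1L] <= age_window[2L])
  in_win <- function(p) p[p$age_months >= age_window[1L] &
                            p$age_months <= age_window[2L], , drop = FALSE]
  a <- in_win(panel_a)
  b <- in_win(panel_b)
  rows <- lapply(variables, function(v) {
    va <- a[[v]][!is.na(a[[v]])]
    vb <- b[[v]][!is.na(b[[v]])]
    if (length(va) < 3L || length(vb) < 3L) {
      data.frame(variable = v, n_a = length(va), n_b = length(vb),
                 p_value = NA_real_, testable = FALSE)
    } else {
      p <- stats::wilcox.test(va, vb, exact = FALSE)$p.value
      data.frame(variable = v, n_a = length(va), n_b = length(vb),
                 p_value = p, testable = TRUE)
    }
  })
  do.call(rbind, rows)
}
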