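# Seeded generators emulating a two-strain mouse lifespan study:
# Gompertz-distributed cohorts with age-dependent postmortem tumor labels,
# survival-curve point tables with digitization-like jitter, and
# cross-sectional organ panels (body/thymus/spleen weight, log2 thymulin
# titer) with declining thymus trajectories. Every generator is a pure
# function of (scenario, seed); streams are scoped with withr::with_seed
# (Mersenne-Twister), so results are reproducible across platforms.

#' Strain scenario for the synthetic-data generators
#'
#' All the knobs needed to emulate one strain: its Gompertz mortality law and
#' cohort size; a logistic-in-age probability that a death carries at least
#' one tumor (postmortem finding, not a competing risk); a multinomial over
#' primary tumor-type labels, with an optional secondary-label rule for tumor
#' types that co-occur with a primary; and per-variable organ trends.
#'
#' @param label Strain label.
#' @param params [gompertz_params()] of the mortality law.
#' @param n0 Default cohort size.
#' @param tumor_midpoint_days Age at which the probability of a death being
#'   tumor-bearing reaches 0.5.
#' @param tumor_steepness_days Logistic scale (days); smaller = steeper rise.
#' @param tumor_type_weights Named non-negative weights over primary tumor
#'   types; normalized to sum to 1.
#' @param tumor_secondary Named list: for a primary label, a named probability
#'   vector of secondary labels attached independently (e.g. carcinomas
#'   arising in papilloma bearers).
#' @param organ Named list of organ-variable trends; each entry is a list
#'   with `form` (`"constant"`, `"linear"`, `"exp-decay"`,
#'   `"logistic-growth"`), `pars`, and `noise_sd` (Gaussian, additive).
#' @param max_organ_age_months Oldest sacrifice age generated (short-lived
#'   strains yield no organ data beyond their lifespan range).
#' @return An object of class `strain_scenario`.
#' @export
strain_scenario <- function(label, params, n0, tumor_midpoint_days,
                            tumor_steepness_days, tumor_type_weights,
                            tumor_secondary = list(), organ = list(),
                            max_organ_age_months = Inf) {
  params <- as_gompertz_params(params)
  if (tumor_steepness_days <= 0) {
    stop("'tumor_steepness_days' must be positive", call. = FALSE)
  }
  w <- tumor_type_weights
  if (is.null(names(w)) || any(w < 0) || sum(w) <= 0) {
    stop("'tumor_type_weights' must be named non-negative weights",
         call. = FALSE)
  }
  w <- w / sum(w)
  for (sec in tumor_secondary) {
    if (any(sec < 0) || any(sec > 1)) {
      stop("secondary-label probabilities must lie in [0,1]", call. = FALSE)
    }
  }
  structure(list(label = label, params = params, n0 = as.integer(n0),
                 tumor_midpoint_days = tumor_midpoint_days,
                 tumor_steepness_days = tumor_steepness_days,
                 tumor_type_weights = w, tumor_secondary = tumor_secondary,
                 organ = organ,
                 max_organ_age_months = max_organ_age_months),
            class = "strain_scenario")
}

#' @export
print.strain_scenario <- function(x, ...) {
  cat("Strain scenario '", x$label, "': N0 = ", x$n0, "\n", sep = "")
  print(x$params)
  cat("  tumor types:", paste(names(x$tumor_type_weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' Default wild-type-like and accelerated-aging-like scenarios
#'
#' A matched pair of scenarios: a wild-type-like strain
#' (mu0 = 0.00014/day, gamma = 0.0049/day, N0 = 69) and an
#' accelerated-aging-like strain with the aging rate increased ~1.57x at
#' essentially unchanged initial mortality (mu0 = 0.00013/day,
#' gamma = 0.0077/day, N0 = 46). Tumor-type weights follow the lifelong
#' postmortem tumor spectra of the emulated study (wild-type: mostly lung
#' adenocarcinomas and lymphomas, 21 tumor-bearing of 69; accelerated:
#' papilloma-dominated, 19 tumor-bearing of 46 with squamous-cell carcinomas
#' attached as secondary labels to papilloma bearers with probability 5/12).
#' Organ trends are package fixtures, not measurements: exponential thymus
#' involution and linear log2-thymulin decline (both ~2x faster in the
#' accelerated strain), logistic body-weight growth and constant spleen
#' weight shared by both strains; the accelerated strain yields no organ
#' data past 18 months because it does not live that long.
#'
#' @return Named list with elements `wt` and `k14`, each a
#'   [strain_scenario()].
#' @export
make_default_scenarios <- function() {
  organ_shared <- list(
    body_weight_g = list(form = "logistic-growth",
                         pars = c(asym = 28, midpoint = 1.5, scale = 1.5),
                         noise_sd = 2),
    spleen_weight_mg = list(form = "constant", pars = c(value = 100),
                            noise_sd = 15))
  wt_organ <- c(organ_shared, list(
    thymus_weight_mg = list(form = "exp-decay", pars = c(w0 = 60, k = 0.055),
                            noise_sd = 4),
    log2_thymulin_titer = list(form = "linear",
                               pars = c(intercept = 5.5, slope = -0.15),
                               noise_sd = 0.5)))
  k14_organ <- c(organ_shared, list(
    # w0 chosen so both strains' thymus trends nearly coincide at the first
    # sacrifice age (3 months) and diverge thereafter
    thymus_weight_mg = list(form = "exp-decay", pars = c(w0 = 72, k = 0.115),
                            noise_sd = 4),
    log2_thymulin_titer = list(form = "linear",
                               pars = c(intercept = 5.5, slope = -0.25),
                               noise_sd = 0.5)))
  wt <- strain_scenario(
    label = "WT-like", params = gompertz_params(0.00014, 0.0049), n0 = 69L,
    tumor_midpoint_days = 800, tumor_steepness_days = 250,
    tumor_type_weights = c(papilloma = 2, squamous_cell_carcinoma = 2,
                           harderian_gland_cystadenocarcinoma = 1,
                           lung_adenocarcinoma = 9, lymphoma = 5,
                           ovarian_serous_cysts = 1,
                           uterine_granulosa_cell_tumor = 1) / 21,
    organ = wt_organ, max_organ_age_months = 21)
  k14 <- strain_scenario(
    label = "K14-like", params = gompertz_params(0.00013, 0.0077), n0 = 46L,
    tumor_midpoint_days = 520, tumor_steepness_days = 200,
    tumor_type_weights = c(papilloma = 12, lung_adenocarcinoma = 2,
                           lung_adenoma = 1, lung_carcinosarcoma = 1,
                           mammary_adenocarcinoma = 1,
                           mesenterial_angioma = 1,
                           uterine_angiosarcoma = 1) / 19,
    tumor_secondary = list(papilloma = c(squamous_cell_carcinoma = 5 / 12)),
    organ = k14_organ, max_organ_age_months = 18)
  list(wt = wt, k14 = k14)
}

# impls draw from the ambient RNG stream; public wrappers scope the seed
generate_cohort_impl <- function(s, n0) {
  u <- stats::runif(n0)
  t <- gompertz_quantile(s$params, u)
  p_tumor <- stats::plogis((t - s$tumor_midpoint_days) / s$tumor_steepness_days)
  has_tumor <- stats::runif(n0) < p_tumor
  labels <- rep(list(character(0)), n0)
  types <- names(s$tumor_type_weights)
  idx <- which(has_tumor)
  if (length(idx) > 0L) {
    primary <- sample(types, length(idx), replace = TRUE,
                      prob = s$tumor_type_weights)
    for (j in seq_along(idx)) {
      lab <- primary[j]
      sec <- s$tumor_secondary[[lab]]
      if (!is.null(sec)) {
        extra <- names(sec)[stats::runif(length(sec)) < sec]
        lab <- c(lab, extra)
      }
      labels[[idx[j]]] <- lab
    }
  }
  cohort(t, event = rep(1L, n0), tumor_labels = labels, group = s$label)
}

#' Generate a lifespan cohort from a strain scenario
#'
#' Lifespans by seeded inverse-CDF Gompertz sampling; each death is then
#' assigned tumor presence by the scenario's logistic-in-age rule and a type
#' by its multinomial (plus any secondary labels). Tumor labels are
#' postmortem annotations only — they never alter the lifespans.
#'
#' @param s A [strain_scenario()].
#' @param seed Integer seed.
#' @param n0 Cohort size; defaults to the scenario's.
#' @return A [cohort()].
#' @export
generate_cohort <- function(s, seed, n0 = s$n0) {
  stopifnot(inherits(s, "strain_scenario"))
  withr::with_seed(as.integer(seed), generate_cohort_impl(s, n0))
}

#' Generate a survival-curve point table with digitization-like noise
#'
#' The empirical step curve of a generated cohort, optionally with Gaussian
#' age-axis jitter emulating the imprecision of digitizing points from a
#' published figure. Ages are re-sorted after jittering and survivor counts
#' kept non-increasing, so the result is always a valid curve.
#'
#' @inheritParams generate_cohort
#' @param digitization_noise_sd Age jitter SD in days (>= 0; 0 = exact curve).
#' @return A [survival_curve()].
#' @export
generate_curve <- function(s, seed, digitization_noise_sd = 0, n0 = s$n0) {
  stopifnot(inherits(s, "strain_scenario"))
  if (digitization_noise_sd < 0) {
    stop("'digitization_noise_sd' must be >= 0", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    coh <- generate_cohort_impl(s, n0)
    curve <- as_survival_curve(coh)
    if (digitization_noise_sd > 0) {
      age <- curve$age_days
      jit <- age[-1L] + stats::rnorm(length(age) - 1L,
                                     sd = digitization_noise_sd)
      jit <- sort(pmax(jit, 1e-6))
      # collapse accidental ties so ages stay strictly increasing
      while (any(diff(jit) <= 0)) {
        jit[which(diff(jit) <= 0) + 1L] <-
          jit[which(diff(jit) <= 0) + 1L] + 1e-6
        jit <- sort(jit)
      }
      surv <- sort(curve$survivors[-1L], decreasing = TRUE)
      curve <- survival_curve(c(0, jit), c(curve$n0, surv), n0 = curve$n0)
    }
    curve
  })
}

organ_trend_value <- function(spec, age_months) {
  p <- spec$pars
  switch(spec$form,
         "constant" = rep(p[["value"]], length(age_months)),
         "linear" = p[["intercept"]] + p[["slope"]] * age_months,
         "exp-decay" = p[["w0"]] * exp(-p[["k"]] * age_months),
         "logistic-growth" = p[["asym"]] /
           (1 + exp(-(age_months - p[["midpoint"]]) / p[["scale"]])),
         stop("unknown organ trend form '", spec$form, "'", call. = FALSE))
}

#' Generate a cross-sectional organ panel
#'
#' Emulates serial-sacrifice data: at each scheduled age, `n_per_age` animals
#' contribute one row with each organ variable drawn from its scenario trend
#' plus Gaussian noise (weights floored at 0.1 of their unit). Ages beyond
#' the scenario's `max_organ_age_months` are dropped.
#'
#' @inheritParams generate_cohort
#' @param sacrifice_schedule_months Ages at sacrifice (default 3, 6, ..., 21).
#' @param n_per_age Animals sacrificed per age (default 10).
#' @return An organ-panel data.frame (see [read_organ_panel_csv()]).
#' @export
generate_organ_panel <- function(s, seed,
                                 sacrifice_schedule_months = seq(3, 21, by = 3),
                                 n_per_age = 10L) {
  stopifnot(inherits(s, "strain_scenario"))
  if (length(sacrifice_schedule_months) == 0L || n_per_age < 1L) {
    stop("need a non-empty schedule and n_per_age >= 1", call. = FALSE)
  }
  sched <- sacrifice_schedule_months[sacrifice_schedule_months <=
                                       s$max_organ_age_months]
  if (length(sched) == 0L) {
    stop("entire schedule lies beyond the scenario's organ age range",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    ages <- rep(sched, each = n_per_age)
    n <- length(ages)
    df <- data.frame(
      animal_id = sprintf("%s_organ_%03d", gsub("\\s+", "_", s$label),
                          seq_len(n)),
      group = s$label, age_months = ages, stringsAsFactors = FALSE)
    for (v in c("body_weight_g", "thymus_weight_mg", "spleen_weight_mg",
                "log2_thymulin_titer")) {
      spec <- s$organ[[v]]
      if (is.null(spec)) {
        df[[v]] <- NA_real_
      } else {
        val <- organ_trend_value(spec, ages) + stats::rnorm(n, sd = spec$noise_sd)
        if (v != "log2_thymulin_titer") val <- pmax(val, 0.1)
        df[[v]] <- val
      }
    }
    df
  })
}

#' Write a complete synthetic fixture set
#'
#' From a single seed, writes the CSV files a full analysis consumes: one
#' cohort and one survival-curve table per strain, and a combined organ
#' panel. File seeds are derived deterministically from `seed`.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param scenarios List with `wt` and `k14` scenarios
#'   (default [make_default_scenarios()]).
#' @param digitization_noise_sd Age jitter for the curve tables (days).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_set <- function(dir, seed, scenarios = make_default_scenarios(),
                              digitization_noise_sd = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  paths <- c(wt_cohort = file.path(dir, "wt_cohort.csv"),
             k14_cohort = file.path(dir, "k14_cohort.csv"),
             wt_curve = file.path(dir, "wt_curve.csv"),
             k14_curve = file.path(dir, "k14_curve.csv"),
             organ_panel = file.path(dir, "organ_panel.csv"))
  write_cohort_csv(generate_cohort(scenarios$wt, seed), paths[["wt_cohort"]])
  write_cohort_csv(generate_cohort(scenarios$k14, seed + 1L),
                   paths[["k14_cohort"]])
  write_curve_csv(generate_curve(scenarios$wt, seed + 2L,
                                 digitization_noise_sd),
                  paths[["wt_curve"]])
  write_curve_csv(generate_curve(scenarios$k14, seed + 3L,
                                 digitization_noise_sd),
                  paths[["k14_curve"]])
  panel <- rbind(generate_organ_panel(scenarios$wt, seed + 4L),
                 generate_organ_panel(scenarios$k14, seed + 5L))
  write_organ_panel_csv(panel, paths[["organ_panel"]])
  invisible(paths)
}
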