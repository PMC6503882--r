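test_that("default scenarios carry the study parameter sets", {
  s <- make_default_scenarios()
  expect_identical(s$wt$params$mu0, 0.00014)
  expect_identical(s$wt$params$gamma, 0.0049)
  expect_identical(s$wt$n0, 69L)
  expect_identical(s$k14$params$mu0, 0.00013)
  expect_identical(s$k14$params$gamma, 0.0077)
  expect_identical(s$k14$n0, 46L)
  # multinomials are normalized; papilloma dominates the accelerated strain
  expect_equal(sum(s$wt$tumor_type_weights), 1, tolerance = 1e-12)
  expect_equal(sum(s$k14$tumor_type_weights), 1, tolerance = 1e-12)
  expect_equal(unname(s$k14$tumor_type_weights["papilloma"]), 12 / 19,
               tolerance = 1e-12)
  expect_equal(unname(s$wt$tumor_type_weights["papilloma"]), 2 / 21,
               tolerance = 1e-12)
  # secondary rule: carcinomas arise in papilloma bearers
  expect_equal(unname(s$k14$tumor_secondary$papilloma), 5 / 12,
               tolerance = 1e-12)
})

test_that("scenario construction validates the tumor model", {
  expect_error(strain_scenario("x", wt_params(), 10, 500, -1,
                               c(papilloma = 1)), "positive")
  expect_error(strain_scenario("x", wt_params(), 10, 500, 100, c(1, 2)),
               "named")
  expect_error(strain_scenario("x", wt_params(), 10, 500, 100,
                               c(papilloma = 1),
                               tumor_secondary = list(papilloma = c(s = 2))),
               "\\[0,1\\]")
})

test_that("generators are pure functions of scenario and seed", {
  s <- make_default_scenarios()
  c1 <- generate_cohort(s$wt, seed = 42)
  c2 <- generate_cohort(s$wt, seed = 42)
  expect_identical(c1$lifespan_days, c2$lifespan_days)
  expect_identical(c1$tumor_labels, c2$tumor_labels)
  expect_false(identical(c1$lifespan_days,
                         generate_cohort(s$wt, seed = 43)$lifespan_days))

  k1 <- generate_curve(s$k14, seed = 9, digitization_noise_sd = 5)
  k2 <- generate_curve(s$k14, seed = 9, digitization_noise_sd = 5)
  expect_identical(k1$age_days, k2$age_days)

  p1 <- generate_organ_panel(s$wt, seed = 3)
  p2 <- generate_organ_panel(s$wt, seed = 3)
  expect_identical(p1, p2)
})

test_that("cohort lifespans reuse the seeded inverse-CDF sampler", {
  s <- make_default_scenarios()
  coh <- generate_cohort(s$wt, seed = 27)
  expect_identical(coh$lifespan_days,
                   sample_lifespans(s$wt$params, 69, seed = 27)$lifespans)
})

test_that("tumor prevalence rises across lifespan terciles", {
  s <- make_default_scenarios()
  big <- generate_cohort(s$wt, seed = 13, n0 = 3000)
  bearing <- lengths(big$tumor_labels) > 0
  terc <- cut(big$lifespan_days,
              quantile(big$lifespan_days, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  prev <- tapply(bearing, terc, mean)
  expect_true(all(diff(prev) > 0))
})

test_that("generated cohorts are refit to within their own intervals", {
  s <- make_default_scenarios()
  hits <- vapply(1:100, function(i) {
    f <- fit_ml(generate_cohort(s$wt, seed = 60000 + i))
    c(gamma = f$ci_gamma[1] <= 0.0049 && 0.0049 <= f$ci_gamma[2],
      mu0 = f$ci_mu0[1] <= 0.00014 && 0.00014 <= f$ci_mu0[2])
  }, c(TRUE, TRUE))
  expect_gte(mean(hits["gamma", ]), 0.9)
  expect_gte(mean(hits["mu0", ]), 0.9)
})

test_that("noiseless curves equal the cohort's empirical step function", {
  s <- make_default_scenarios()
  coh <- generate_cohort(s$k14, seed = 4)
  curve <- generate_curve(s$k14, seed = 4, digitization_noise_sd = 0)
  expect_identical(curve$age_days, as_survival_curve(coh)$age_days)
  expect_identical(curve$survivors, as_survival_curve(coh)$survivors)
})

test_that("jittered curves stay valid and still support fitting", {
  s <- make_default_scenarios()
  # digitization robustness: the jittered-curve estimate stays close to the
  # same cohort's exact-curve estimate (cohort sampling noise cancels)
  ok <- vapply(1:30, function(i) {
    cv <- generate_curve(s$wt, seed = 70000 + i, digitization_noise_sd = 5)
    stopifnot(all(diff(cv$age_days) > 0), all(diff(cv$survivors) <= 0))
    cv0 <- generate_curve(s$wt, seed = 70000 + i, digitization_noise_sd = 0)
    f <- tryCatch(fit_curve(cv), error = function(e) NULL)
    g0 <- fit_curve(cv0)$params$gamma
    !is.null(f) && abs(f$params$gamma - g0) / g0 < 0.10
  }, TRUE)
  expect_gte(mean(ok), 0.8)
  expect_error(generate_curve(s$wt, 1, digitization_noise_sd = -1), ">= 0")
})

test_that("organ panels follow the scenario trends", {
  s <- make_default_scenarios()
  pw <- generate_organ_panel(s$wt, seed = 5)
  pk <- generate_organ_panel(s$k14, seed = 6)
  # short-lived strain contributes no data past 18 months
  expect_lte(max(pk$age_months), 18)
  expect_identical(max(pw$age_months), 21)
  expect_identical(sum(pw$age_months == 3), 10L)

  # constant spleen: slope of per-age means within 2 SE of zero
  mtab <- aggregate(spleen_weight_mg ~ age_months, pw, mean)
  fitl <- summary(lm(spleen_weight_mg ~ age_months, mtab))$coefficients
  expect_lt(abs(fitl["age_months", "Estimate"]),
            2 * fitl["age_months", "Std. Error"])

  # thymus involution: strictly meaningful decline in both strains
  thy <- aggregate(thymus_weight_mg ~ age_months, pw, mean)
  expect_lt(thy$thymus_weight_mg[nrow(thy)], thy$thymus_weight_mg[1] / 2)
})

test_that("thymulin divergence grows with age across seeds", {
  s <- make_default_scenarios()
  res <- vapply(1:20, function(i) {
    pa <- generate_organ_panel(s$wt, seed = 300 + i)
    pb <- generate_organ_panel(s$k14, seed = 400 + i)
    early <- age_interval_compare(pa, pb, c(3, 3))
    late <- age_interval_compare(pa, pb, c(15, 18))
    c(early = early$p_value[early$variable == "log2_thymulin_titer"],
      late = late$p_value[late$variable == "log2_thymulin_titer"])
  }, c(0, 0))
  expect_gt(mean(res["early", ] > 0.05), 0.5)
  expect_gt(mean(res["late", ] < 0.05), 0.5)
})

test_that("CSV round trips preserve cohorts, curves and panels", {
  s <- make_default_scenarios()
  dir <- withr::local_tempdir()

  coh <- generate_cohort(s$k14, seed = 8)
  path <- file.path(dir, "coh.csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$lifespan_days, coh$lifespan_days, tolerance = 1e-12)
  expect_identical(back$tumor_labels, coh$tumor_labels)
  expect_identical(back$group, coh$group)

  cv <- generate_curve(s$wt, seed = 8)
  cpath <- file.path(dir, "curve.csv")
  write_curve_csv(cv, cpath)
  cback <- read_curve_csv(cpath, n0 = cv$n0)
  expect_equal(cback$age_days, cv$age_days, tolerance = 1e-10)
  expect_equal(cback$survivors, cv$survivors, tolerance = 1e-10)

  paths <- write_fixture_set(file.path(dir, "fix"), seed = 1)
  expect_true(all(file.exists(paths)))
  panel <- read_organ_panel_csv(paths[["organ_panel"]])
  expect_setequal(unique(panel$group), c("WT-like", "K14-like"))
  two <- read_cohort_csv(paths[["wt_cohort"]])
  expect_s3_class(two, "cohort")
})
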