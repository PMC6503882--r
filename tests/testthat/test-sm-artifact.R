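test_that("subsampling a single population yields a strong negative artifact", {
  ref <- build_reference_by_subsampling(wt_params(), n_sub = 50,
                                        n_reps = 200, seed = 11)
  expect_s3_class(ref, "sm_reference")
  expect_identical(ref$provenance, "subsampled-single-population")
  expect_lt(ref$slope, 0)
  expect_lte(ref$r, -0.8)
  # cross-check slope, intercept and r against a sums-based OLS
  by_hand <- ols_by_hand(ref$points$gamma, ref$points$ln_mu0)
  expect_equal(ref$slope, by_hand$slope, tolerance = 1e-10)
  expect_equal(ref$intercept, by_hand$intercept, tolerance = 1e-10)
  expect_equal(ref$r, by_hand$r, tolerance = 1e-10)
})

test_that("subsampling is deterministic given the seed and validates input", {
  ref1 <- build_reference_by_subsampling(k14_params(), 30, 40, seed = 2)
  ref2 <- build_reference_by_subsampling(k14_params(), 30, 40, seed = 2)
  expect_identical(ref1$points, ref2$points)
  expect_identical(ref1$slope, ref2$slope)
  expect_error(build_reference_by_subsampling(k14_params(), 5, 40, 1), ">= 10")
  expect_error(build_reference_by_subsampling(k14_params(), 30, 10, 1), ">= 20")
})

test_that("huge subsamples collapse the cloud onto the generating point", {
  wt <- wt_params()
  ref <- build_reference_by_subsampling(wt, n_sub = 200000, n_reps = 20,
                                        seed = 31)
  expect_lt(diff(range(ref$points$gamma)), 0.01 * wt$gamma)
  expect_lt(diff(range(ref$points$ln_mu0)), 0.01 * abs(log(wt$mu0)))
})

test_that("a reference from fits on an exact line recovers that line", {
  slope <- -500
  intercept <- -8
  gammas <- c(0.004, 0.006, 0.009)
  fits <- lapply(gammas, function(g) {
    mu0 <- exp(intercept + slope * g)
    fit_result(mu0, g, ci_mu0 = mu0 * c(0.8, 1.2), ci_gamma = g * c(0.9, 1.1))
  })
  ref <- build_reference_from_fits(fits)
  expect_equal(ref$slope, slope, tolerance = 1e-9)
  expect_equal(ref$intercept, intercept, tolerance = 1e-9)
  expect_identical(ref$provenance, "pooled-controls")
})

test_that("degenerate fit sets are refused", {
  f <- wt_table_fit()
  expect_error(build_reference_from_fits(list(f, f, f)), "degenerate")
  expect_error(build_reference_from_fits(list(f, f)), "at least 3")
})

test_that("pooled-fit and subsampling references agree on the same law", {
  wt <- wt_params()
  sub_seeds <- withr::with_seed(600L, sample.int(1e6, 60))
  fits <- lapply(sub_seeds, function(s) fit_ml(sample_lifespans(wt, 50, s)))
  ref_fits <- build_reference_from_fits(fits)
  ref_sub <- build_reference_by_subsampling(wt, 50, 200, seed = 11)
  # same artifact: slopes agree within the scatter of the point clouds
  se_slope <- abs(ref_fits$slope) / sqrt(length(fits))
  expect_lt(abs(ref_fits$slope - ref_sub$slope), 4 * se_slope)
  expect_lt(ref_fits$r, -0.8)
})

test_that("change vectors do the published arithmetic and are antisymmetric", {
  wt <- wt_table_fit()
  k14 <- k14_table_fit()
  v <- change_vector(wt, k14)
  expect_equal(v$d_gamma, 0.0028, tolerance = 1e-12)
  expect_equal(v$d_ln_mu0, log(13 / 14), tolerance = 1e-12)
  expect_false(v$gamma_overlap)
  expect_true(v$mu0_overlap)
  back <- change_vector(k14, wt)
  expect_equal(back$d_gamma, -v$d_gamma, tolerance = 1e-15)
  expect_equal(back$d_ln_mu0, -v$d_ln_mu0, tolerance = 1e-15)
  none <- change_vector(wt, wt)
  expect_identical(none$d_gamma, 0)
  expect_identical(none$d_ln_mu0, 0)
})

test_that("decomposition is exact and classification handles edge vectors", {
  ref <- build_reference_by_subsampling(wt_params(), 50, 100, seed = 4)
  wt <- wt_table_fit()
  k14 <- k14_table_fit()
  v <- change_vector(wt, k14)
  cl <- classify_vector(v, ref)
  expect_equal(unname(cl$along + cl$orth), unname(cl$v_norm),
               tolerance = 1e-12)
  expect_equal(cl$orth_share + sum(cl$along^2) / sum(cl$v_norm^2), 1,
               tolerance = 1e-12)

  # a vector lying exactly on the reference line is pure artifact
  dg <- 0.001
  on_line <- fit_result(wt$params$mu0 * exp(ref$slope * dg),
                        wt$params$gamma + dg,
                        ci_mu0 = wt$ci_mu0 * exp(ref$slope * dg),
                        ci_gamma = wt$ci_gamma + dg)
  cl_line <- classify_vector(change_vector(wt, on_line), ref)
  expect_lt(cl_line$orth_share, 1e-20)
  expect_identical(cl_line$label, "largely_artifactual")

  # the zero vector is null
  expect_identical(classify_vector(change_vector(wt, wt), ref)$label, "null")
})

test_that("a non-negative subsampled reference slope is refused", {
  bad <- suppressWarnings(
    sm_reference(slope = 50, intercept = -9, r = 0.5,
                 points = data.frame(gamma = c(0.004, 0.005, 0.006),
                                     ln_mu0 = c(-9, -8.8, -8.9)),
                 provenance = "subsampled-single-population"))
  v <- change_vector(wt_table_fit(), k14_table_fit())
  expect_error(classify_vector(v, bad), "negative slope")
})

test_that("user-supplied references need plane scales", {
  ref <- sm_reference(slope = -600, intercept = -6, provenance = "user-supplied")
  v <- change_vector(wt_table_fit(), k14_table_fit())
  expect_error(classify_vector(v, ref), "scales")
  ref2 <- sm_reference(slope = -600, intercept = -6,
                       provenance = "user-supplied",
                       sd_gamma = 6e-4, sd_ln_mu0 = 0.4)
  expect_s3_class(classify_vector(v, ref2), "sm_classification")
})

test_that("subsample-pair change vectors classify as artifact or null", {
  wt <- wt_params()
  ref <- build_reference_by_subsampling(wt, 50, 200, seed = 11)
  labels <- vapply(1:100, function(i) {
    fa <- fit_ml(sample_lifespans(wt, 50, seed = 10000 + 2 * i))
    fb <- fit_ml(sample_lifespans(wt, 50, seed = 10001 + 2 * i))
    classify_vector(change_vector(fa, fb), ref)$label
  }, "")
  expect_gte(mean(labels %in% c("largely_artifactual", "null")), 0.9)
})

test_that("a real aging-rate increase is the majority classification", {
  # gamma raised 1.57x at fixed mu0, study-sized cohorts
  wt <- wt_params()
  accel <- gompertz_params(wt$mu0, wt$gamma * 1.57)
  ref <- build_reference_by_subsampling(wt, 50, 200, seed = 11)
  labels <- vapply(1:100, function(i) {
    fc <- fit_ml(sample_lifespans(wt, 69, seed = 20000 + 2 * i))
    ft <- fit_ml(sample_lifespans(accel, 46, seed = 20001 + 2 * i))
    classify_vector(change_vector(fc, ft), ref)$label
  }, "")
  expect_gt(mean(labels == "aging_rate_change"), 0.5)
})

test_that("results serialize to data frames and JSON", {
  ref <- build_reference_by_subsampling(wt_params(), 30, 40, seed = 2)
  df <- as.data.frame(ref)
  expect_identical(df$n_points, 40L)
  cl <- classify_vector(change_vector(wt_table_fit(), k14_table_fit()), ref)
  js <- sm_to_json(cl)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$label, cl$label)
  expect_equal(parsed$orth_share, cl$orth_share, tolerance = 1e-12)
})
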