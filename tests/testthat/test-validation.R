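test_that("bias, RMSPE and coverage match hand arithmetic", {
  expect_equal(bias(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bias(c(1.5, 2.5), c(1, 2)), 0.5)
  expect_equal(bias(c(1, 2, 3), c(0, 2, 5)), -1 / 3)

  expect_equal(rmspe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmspe(3, 1), 2)
  expect_equal(rmspe(c(1, 2, 3), c(0, 2, 5)), sqrt(5 / 3))
  expect_equal(rmspe(c(1, 2, 3), c(0, 2, 5)), 1.2910, tolerance = 1e-4)

  expect_equal(coverage(rep(-Inf, 4), rep(Inf, 4), rnorm(4)), 100)
  expect_equal(coverage(c(1, 1), c(2, 2), c(5, -3)), 0)
  expect_equal(coverage(rep(0, 4), rep(1, 4), c(0.5, 0.2, 0.9, 7)), 75)
  expect_equal(coverage(0, 1, 1), 100)  # closed intervals

  expect_error(bias(1:3, 1:2), "equal length")
  expect_error(coverage(c(2, 0), c(1, 1), c(0, 0)), "malformed")
})

test_that("squared RMSPE dominates squared bias on arbitrary inputs", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    p <- rnorm(n, sd = runif(1, 0.1, 5))
    o <- rnorm(n, sd = runif(1, 0.1, 5))
    expect_gte(rmspe(p, o)^2, bias(p, o)^2 - 1e-12)
  }
  # permutation invariance of all three metrics
  p <- rnorm(20); o <- rnorm(20); lo <- o - 1; hi <- o + 1
  perm <- sample(20)
  expect_equal(bias(p[perm], o[perm]), bias(p, o))
  expect_equal(rmspe(p[perm], o[perm]), rmspe(p, o))
  expect_equal(coverage(lo[perm], hi[perm], o[perm]), coverage(lo, hi, o))
})

test_that("OLS cross-validation is exact on noiseless linear data", {
  sites <- make_obs_sites(n_tubes = 25, n_monitors = 5, n_colocated = 2,
                          seed = 101, spec = covariate_spec())
  # concentrations exactly log-linear in the modelled surface
  sites$no2_ugm3 <- exp(2 + 0.5 * log(sites$pcm_no2_ugm3))
  v <- suppressWarnings(loocv(sites, covariate_spec(), fit_method = "ols"))
  expect_lt(abs(v$bias), 1e-8)
  expect_lt(v$rmspe, 1e-8)
  # zero-width intervals at machine precision: allow one-ulp misses
  expect_gte(v$coverage_pct, 90)
})

test_that("OLS cross-validation attains near-nominal coverage on iid data", {
  sites <- make_obs_sites(n_tubes = 70, n_monitors = 10, n_colocated = 4,
                          seed = 111, spec = covariate_spec(),
                          params = true_params(
                            c(`(Intercept)` = 2, log_modelled = 0.5),
                            sigma2 = 0.09, nu2 = 0.999, rho = 200))
  # rho huge and nu2 ~ 1: essentially iid Gaussian noise around the mean
  v <- loocv(sites, covariate_spec(), fit_method = "ols")
  expect_gt(v$coverage_pct, 85)
  expect_lt(v$coverage_pct, 100)
  expect_lt(abs(v$bias), 0.15)
})

test_that("REML cross-validation is deterministic and summarises correctly", {
  sites <- make_obs_sites(n_tubes = 30, n_monitors = 6, n_colocated = 2,
                          seed = 121)
  spec <- covariate_spec(environment = TRUE)
  v1 <- loocv(sites, spec, fit_method = "reml", seed = 3)
  v2 <- loocv(sites, spec, fit_method = "reml", seed = 3)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_equal(v1$n_folds + v1$n_skipped, nrow(sites))
  expect_s3_class(v1, "fusion_loocv")
  df <- as.data.frame(v1)
  expect_equal(df$rmspe, v1$rmspe)
  expect_output(print(v1), "RMSPE")
})

test_that("a single-model comparison table has one labelled row", {
  sites <- make_obs_sites(n_tubes = 25, n_monitors = 5, n_colocated = 2,
                          seed = 131, spec = covariate_spec())
  tab <- compare_models(sites,
                        list(m = list(label = "plain", spec = covariate_spec(),
                                      method = "ols")))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$label, "plain")
  expect_true(all(c("bias", "rmspe", "coverage_pct") %in% names(tab)))
})

test_that("the monitor/tube indicator is immaterial when its true effect is null", {
  spec_gen <- covariate_spec(environment = TRUE)
  params <- true_params(
    c(`(Intercept)` = 1.9, log_modelled = 0.594, env_roadside = -0.15,
      env_rural = -1.021, env_special = -0.39, env_urban_background = -0.531),
    sigma2 = 0.057, nu2 = 0.232, rho = 12.852)
  sites <- make_obs_sites(n_tubes = 50, n_monitors = 10, n_colocated = 4,
                          seed = 141, spec = spec_gen, params = params)
  # one rural singleton fold is skipped identically in both runs
  v_without <- suppressWarnings(loocv(sites, spec_gen, fit_method = "reml",
                                      seed = 5))
  v_with <- suppressWarnings(loocv(sites,
                                   covariate_spec(source = TRUE,
                                                  environment = TRUE),
                                   fit_method = "reml", seed = 5))
  expect_lt(abs(v_with$rmspe - v_without$rmspe) / v_without$rmspe, 0.02)
})

test_that("the modelled-surface baseline fits the mean log-ratio adjustment", {
  sites <- make_obs_sites(n_tubes = 40, n_monitors = 8, n_colocated = 3,
                          seed = 151)
  b <- pcm_baseline(sites)
  expect_s3_class(b, "fusion_loocv")

  # full-data adjustment coefficient = difference of group mean log-ratios
  ratio <- log(sites$no2_ugm3) - log(sites$pcm_no2_ugm3)
  road <- sites$environment %in% c("roadside", "kerbside")
  fit <- lm(ratio ~ I(as.numeric(road)))
  expect_equal(unname(coef(fit)[2]),
               mean(ratio[road]) - mean(ratio[!road]), tolerance = 1e-10)

  # baseline is exact when the modelled surface equals the observations
  s2 <- sites; s2$pcm_no2_ugm3 <- s2$no2_ugm3
  b2 <- suppressWarnings(pcm_baseline(s2))
  expect_lt(abs(b2$bias), 1e-10)
  expect_lt(b2$rmspe, 1e-10)
})

test_that("data-source comparison respects subset structure", {
  spec <- covariate_spec(spatial_interaction = TRUE)
  sites <- make_obs_sites(n_tubes = 25, n_monitors = 10, n_colocated = 4,
                          seed = 161, spec = covariate_spec(source = TRUE,
                                                            environment = TRUE))
  tab <- compare_data_sources(sites, spec, subsets = c("monitors", "both"),
                              n_burn = 100, n_keep = 150, seed = 2)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n_fit, c(10L, 35L))
  expect_equal(tab$n_predicted, rep(nrow(sites), 2))
  expect_true(all(tab$rmspe > 0))
  expect_error(compare_data_sources(sites[sites$source == "tube", ], spec,
                                    subsets = "monitors"),
               "fewer than 10")
})

test_that("the standard model list enumerates the nine comparison fits", {
  specs <- standard_model_specs()
  expect_length(specs, 9L)
  expect_equal(vapply(specs, `[[`, "", "method")[1:3],
               c(model1 = "mcmc", model2 = "reml", model3 = "ols"))
  expect_true(specs$model8$spec$spatial_interaction)
  expect_false(specs$model9$spec$source)
  expect_true(all(vapply(specs, function(m) nzchar(m$label), logical(1))))
})
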