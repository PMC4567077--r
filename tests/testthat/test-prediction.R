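test_that("kriging interpolates exactly at observation sites and reverts to the prior far away", {
  coords <- rbind(c(0, 0), c(1000, 400), c(2300, 1800))
  D <- distance_matrix(coords)
  rho <- 1.7; sigma2 <- 0.6
  Sinv <- solve(exp(-rho * D))
  phi <- c(0.4, -0.2, 0.7)

  # prediction at observation site 2: a noiseless field is interpolated
  cross <- matrix(D[2, ], 1)
  k <- krige_phi(phi, sigma2, rho, Sinv, cross, matrix(0, 1, 1), n_draws = 3)
  expect_equal(unname(k$mean), phi[2], tolerance = 1e-8)
  expect_equal(k$cov[1, 1], 0, tolerance = 1e-8)
  expect_true(all(abs(k$draws - phi[2]) < 1e-4))

  # far beyond the effective range: prior mean 0, prior variance sigma2
  far <- matrix(c(50, 51, 52), 1)
  kf <- krige_phi(phi, sigma2, rho, Sinv, far, matrix(0, 1, 1))
  expect_lt(abs(kf$mean), 1e-8)
  expect_equal(kf$cov[1, 1], sigma2, tolerance = 1e-8)
})

test_that("kriging matches hand conditional-Gaussian algebra (N = 1, m = 2)", {
  D <- matrix(c(0, 2, 2, 0), 2)
  rho <- 0.9; sigma2 <- 0.3
  S <- exp(-rho * D)
  phi <- c(0.5, -0.1)
  cross <- matrix(c(0.7, 1.4), 1)   # distances to the two sites

  k <- krige_phi(phi, sigma2, rho, solve(S), cross, matrix(0, 1, 1))
  # by-hand conditional MVN for the 3-point joint covariance
  c_vec <- exp(-rho * c(0.7, 1.4))
  mu_or <- drop(c_vec %*% solve(S) %*% phi)
  v_or <- sigma2 * (1 - drop(c_vec %*% solve(S) %*% c_vec))
  expect_equal(unname(k$mean), mu_or, tolerance = 1e-8)
  expect_equal(k$cov[1, 1], v_or, tolerance = 1e-8)
})

test_that("the observation step adds exactly the nugget", {
  Zs <- cbind(1, c(0.5, 2))
  alpha <- c(1, 0.4)
  phi_star <- c(0.2, -0.3)
  mu <- drop(Zs %*% alpha) + phi_star

  # variance-zero limit is exact
  set.seed(21)
  expect_equal(predict_y(alpha, phi_star, Zs, sigma2 = 1e-30, nu2 = 1e-30),
               mu, tolerance = 1e-10)

  sigma2 <- 0.4; nu2 <- 0.5
  draws <- t(replicate(5000, predict_y(alpha, phi_star, Zs, sigma2, nu2)))
  dev <- sweep(draws, 2, mu)
  expect_equal(apply(dev, 2, var), rep(sigma2 * nu2, 2),
               tolerance = 4 * sqrt(2 / 5000) / (sigma2 * nu2) * (sigma2 * nu2))
  expect_lt(max(abs(colMeans(dev))), 4 * sqrt(sigma2 * nu2 / 5000))
})

test_that("prediction summaries are quantile-equivariant under exp", {
  x <- c(2, 2, 2, 2, 2)
  s <- summarize_predictions(matrix(x, 5, 1))
  expect_equal(s$median_log, 2)
  expect_equal(s$sd_log, 0)
  expect_equal(s$lo_log, 2)
  expect_equal(s$hi_log, 2)

  set.seed(22)
  draws <- matrix(rnorm(20000, 3, 0.3), ncol = 2)
  s2 <- summarize_predictions(draws)
  expect_equal(s2$median_log, c(3, 3), tolerance = 0.02)
  expect_equal(s2$sd_log, c(0.3, 0.3), tolerance = 0.02)
  expect_equal(s2$median_ugm3, exp(s2$median_log))   # exact by construction
  expect_equal(s2$lo_ugm3, exp(s2$lo_log))
  expect_true(all(s2$lo_log <= s2$median_log & s2$median_log <= s2$hi_log))
})

test_that("posterior prediction behaves coherently on a fitted model", {
  spec <- covariate_spec(source = TRUE, environment = TRUE)
  sites <- make_obs_sites(n_tubes = 40, n_monitors = 8, n_colocated = 3,
                          seed = 71, spec = spec)
  fit <- fit_fusion(sites, spec, n_burn = 300, n_keep = 400, seed = 3)

  # two co-located prediction points share the mean surface draw for draw
  nd <- sites[c(5, 5), ]
  p <- predict(fit, nd, include_nugget = FALSE, seed = 4)
  dr <- attr(p, "draws")
  expect_equal(dr[, 1], dr[, 2], tolerance = 1e-8)

  # the nugget widens every interval
  p_lat <- predict(fit, sites[1:8, ], include_nugget = FALSE, seed = 5)
  p_obs <- predict(fit, sites[1:8, ], include_nugget = TRUE, seed = 5)
  expect_true(all(p_obs$sd_log > p_lat$sd_log - 1e-12))

  # in-sample intervals cover the training data generously
  p_all <- predict(fit, sites, seed = 6)
  expect_gte(coverage(p_all$lo_log, p_all$hi_log, fit$Y), 95)
})

test_that("grid prediction forces the exposure-relevant environments", {
  spec <- covariate_spec(source = TRUE, environment = TRUE)
  cfg <- synthetic_config(n_tubes = 110, n_monitors = 10, n_colocated = 4,
                          seed = 81)
  grid <- generate_grid(cfg)
  sites <- generate_sites(cfg, grid)
  sites <- simulate_observations(sites, spec, cfg$true_params, seed = 81)
  fit <- fit_fusion(sites, spec, n_burn = 300, n_keep = 400, seed = 8)

  pg <- predict_grid(fit, grid, seed = 9)
  expect_equal(nrow(pg), nrow(grid))
  expect_true(all(is.finite(pg$median_log)))
  expect_true(all(is.finite(pg$sd_log)))
  # urban background sits above rural on the concentration scale
  expect_gt(median(pg$median_ugm3[pg$urban]),
            median(pg$median_ugm3[!pg$urban]))

  bad <- grid; bad$pcm_no2_ugm3[1] <- NA
  expect_error(predict_grid(fit, bad), "pcm")
})

test_that("grid predictions track the generating surface in the low-noise limit", {
  spec <- covariate_spec(environment = TRUE)
  params <- true_params(
    c(`(Intercept)` = 1.9, log_modelled = 0.594, env_roadside = -0.15,
      env_rural = -1.021, env_special = -0.39, env_urban_background = -0.531),
    sigma2 = 1e-4, nu2 = 0.232, rho = 12.852)
  cfg <- synthetic_config(n_tubes = 110, n_monitors = 10, n_colocated = 4,
                          seed = 91, true_params = params)
  grid <- generate_grid(cfg)
  sites <- generate_sites(cfg, grid)
  sites <- simulate_observations(sites, spec, params, seed = 91)
  fit <- fit_fusion(sites, spec, n_burn = 300, n_keep = 400, seed = 10)
  pg <- predict_grid(fit, grid, seed = 11)

  # generating mean at the grid under the same environment forcing
  ndg <- data.frame(easting_m = grid$easting_m, northing_m = grid$northing_m,
                    pcm_no2_ugm3 = grid$pcm_no2_ugm3, source = "tube",
                    environment = ifelse(grid$urban, "urban_background",
                                         "rural"))
  Zg <- build_design_matrix(ndg, spec, template = fit$Z)
  truth <- drop(Zg %*% params$alpha[colnames(Zg)])
  expect_gt(cor(pg$median_log, truth), 0.9)
})
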