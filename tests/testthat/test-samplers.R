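# Brute-force oracles for every full-conditional update, on toy problems
# small enough to solve by independent algebra or quadrature.

test_that("alpha update matches the Bayesian linear-regression closed form", {
  set.seed(1)
  Z <- cbind(1, c(-1, 0, 2))
  Y <- c(1.2, 0.4, 2.5)
  phi <- c(0.1, -0.2, 0.05)
  sigma2 <- 0.5; nu2 <- 0.4; v <- 10
  tau <- nu2 * sigma2

  # independent oracle: textbook posterior with explicit solve()
  V_post <- solve(t(Z) %*% Z / tau + diag(1 / v, 2))
  m_post <- V_post %*% (t(Z) %*% (Y - phi) / tau)

  fc <- geofuse:::alpha_conditional(Y, Z, phi, sigma2, nu2, v)
  expect_equal(fc$mean, drop(m_post), tolerance = 1e-10)
  expect_equal(chol2inv(fc$chol_prec), V_post, tolerance = 1e-10)

  # flat-prior limit: conditional mean -> OLS of (Y - phi) on Z
  fc_flat <- geofuse:::alpha_conditional(Y, Z, phi, sigma2, nu2, 1e12)
  expect_equal(fc_flat$mean, drop(qr.solve(Z, Y - phi)), tolerance = 1e-6)

  # posterior variance shrinks as the observation variance decreases
  fc_small <- geofuse:::alpha_conditional(Y, Z, phi, sigma2 / 100, nu2, v)
  expect_true(all(diag(chol2inv(fc_small$chol_prec)) <
                  diag(chol2inv(fc$chol_prec))))

  # sampled moments agree with the oracle within Monte-Carlo error
  draws <- t(replicate(4000, sample_alpha(Y, Z, phi, sigma2, nu2, v)))
  se <- sqrt(diag(V_post) / 4000)
  expect_true(all(abs(colMeans(draws) - drop(m_post)) < 4 * se))
  expect_equal(cov(draws), V_post, tolerance = 0.15)
})

test_that("phi update matches joint-Gaussian conditioning on a 2-site problem", {
  set.seed(2)
  Z <- cbind(c(1, 1), c(0.5, -1))
  alpha <- c(2, 0.7)
  Y <- c(2.9, 1.1)
  sigma2 <- 0.8; nu2 <- 0.3
  S <- rbind(c(1, 0.6), c(0.6, 1))

  # oracle: condition the joint MVN of (phi, Y) by covariance algebra,
  # a different route from the precision-form implementation
  C_yy <- sigma2 * S + nu2 * sigma2 * diag(2)
  C_py <- sigma2 * S
  mu_or <- C_py %*% solve(C_yy, Y - Z %*% alpha)
  V_or <- sigma2 * S - C_py %*% solve(C_yy, t(C_py))

  fc <- geofuse:::phi_conditional(Y, Z, alpha, sigma2, nu2, solve(S))
  expect_equal(fc$mean, drop(mu_or), tolerance = 1e-8)
  expect_equal(chol2inv(fc$chol_prec), V_or, tolerance = 1e-8)

  # prior-dominates limit: huge nugget pulls the conditional mean to zero
  fc_big <- geofuse:::phi_conditional(Y, Z, alpha, sigma2, 1e8, solve(S))
  expect_lt(max(abs(fc_big$mean)), 1e-6)

  # zero residual and a tiny nugget: draws concentrate near zero
  Y0 <- drop(Z %*% alpha)
  d0 <- replicate(200, sample_phi(Y0, Z, alpha, sigma2, 1e-6, solve(S)))
  expect_lt(max(abs(d0)), 0.05)
})

test_that("sigma2 update has the hand-derived inverse-gamma shape and scale", {
  Z <- cbind(c(1, 1))
  alpha <- 1.5
  Y <- c(2.0, 1.2)
  phi <- c(0.3, -0.4)
  nu2 <- 0.25
  S <- rbind(c(1, 0.5), c(0.5, 1))
  Sinv <- solve(S)
  qf <- drop(phi %*% Sinv %*% phi)
  a <- 0.001; b <- 0.001

  fc <- geofuse:::sigma2_conditional(Y, Z, alpha, phi, nu2, qf, a, b)
  # by hand: shape a + m; scale b + (phi' Sinv phi + ||r||^2 / nu2) / 2
  r <- Y - drop(Z %*% alpha) - phi
  expect_equal(fc$shape, a + 2)
  expect_equal(fc$scale, b + 0.5 * (qf + sum(r^2) / nu2), tolerance = 1e-12)

  # zero quadratic forms: draw ~ InvGamma(a + m, b)
  fc0 <- geofuse:::sigma2_conditional(drop(Z %*% alpha), Z, alpha, c(0, 0),
                                      nu2, 0, a, b)
  expect_equal(fc0$scale, b)

  # Monte-Carlo mean matches scale / (shape - 1)
  set.seed(3)
  draws <- replicate(5000, sample_sigma2(Y, Z, alpha, phi, nu2, qf, a, b))
  mu <- fc$scale / (fc$shape - 1)
  sd_ig <- fc$scale / ((fc$shape - 1) * sqrt(fc$shape - 2))
  expect_lt(abs(mean(draws) - mu), 4 * sd_ig / sqrt(5000))
})

test_that("nu2 Metropolis step targets its full conditional (grid quadrature)", {
  set.seed(4)
  m <- 5
  Z <- cbind(rep(1, m))
  alpha <- 0
  phi <- rep(0, m)
  sigma2 <- 0.2
  Y <- c(0.31, -0.45, 0.12, 0.6, -0.2)
  ss <- sum(Y^2)

  # zero-step proposal equals the current value and is always accepted
  for (i in 1:5)
    expect_true(sample_nu2(Y, Z, alpha, phi, sigma2, 0.5, step = 0)$accepted)

  # long MH run at fixed conditionals vs numerically normalised density
  grid <- seq(1e-4, 1 - 1e-4, length.out = 4001)
  dens <- exp(-m / 2 * log(grid * sigma2) - ss / (2 * grid * sigma2))
  dens <- dens / sum(dens * diff(grid)[1])
  mean_or <- sum(grid * dens) * diff(grid)[1]
  p_half_or <- sum(dens[grid < 0.5]) * diff(grid)[1]

  n_it <- 30000
  cur <- 0.5
  out <- numeric(n_it)
  for (i in seq_len(n_it)) {
    cur <- sample_nu2(Y, Z, alpha, phi, sigma2, cur, step = 1.5)$nu2
    out[i] <- cur
  }
  out <- out[-(1:2000)]
  expect_equal(mean(out), mean_or, tolerance = 0.03)
  expect_equal(mean(out < 0.5), p_half_or, tolerance = 0.03)
})

test_that("rho update matches enumerate-and-normalise on a 3-candidate problem", {
  coords <- rbind(c(0, 0), c(800, 600))  # 1 km apart
  D <- distance_matrix(coords)
  rho_grid <- c(0.5, 2, 8)
  cache <- build_correlation_cache(D, rho_grid)
  phi <- c(0.9, 0.7)
  sigma2 <- 0.5

  # oracle: full multivariate normal density of phi under each candidate,
  # via det() and solve(), normalised directly
  dens <- sapply(rho_grid, function(r) {
    S <- exp(-r * D)
    det(2 * pi * sigma2 * S)^(-1 / 2) *
      exp(-drop(phi %*% solve(sigma2 * S) %*% phi) / 2)
  })
  p_or <- dens / sum(dens)

  expect_equal(geofuse:::rho_conditional(phi, sigma2, cache), p_or,
               tolerance = 1e-8)

  set.seed(5)
  n <- 10000
  freq <- tabulate(replicate(n, sample_rho(phi, sigma2, cache)), 3) / n
  se <- sqrt(p_or * (1 - p_or) / n)
  expect_true(all(abs(freq - p_or) < 3 * se + 1e-12))

  # with phi = 0 the conditional depends on the determinant alone
  p0 <- geofuse:::rho_conditional(c(0, 0), sigma2, cache)
  det_or <- sapply(rho_grid, function(r) det(exp(-r * D))^(-1 / 2))
  expect_equal(p0, det_or / sum(det_or), tolerance = 1e-10)

  # single-candidate grid always returns index 1
  cache1 <- build_correlation_cache(D, 2)
  expect_equal(unique(replicate(20, sample_rho(phi, sigma2, cache1))), 1L)
})

test_that("full conditionals are equivariant under site relabelling", {
  set.seed(6)
  m <- 6
  coords <- toy_coords(m, seed = 7)
  D <- distance_matrix(coords)
  Z <- cbind(1, rnorm(m))
  Y <- rnorm(m, 2)
  alpha <- c(2, 0.3)
  phi <- rnorm(m, 0, 0.3)
  sigma2 <- 0.4; nu2 <- 0.3
  perm <- c(3, 1, 6, 2, 5, 4)

  cache <- build_correlation_cache(D, c(0.5, 2, 8))
  cache_p <- build_correlation_cache(D[perm, perm], c(0.5, 2, 8))

  fc <- geofuse:::phi_conditional(Y, Z, alpha, sigma2, nu2, cache$Sinv[[2]])
  fc_p <- geofuse:::phi_conditional(Y[perm], Z[perm, ], alpha, sigma2, nu2,
                                    cache_p$Sinv[[2]])
  expect_equal(fc_p$mean, fc$mean[perm], tolerance = 1e-8)

  expect_equal(geofuse:::rho_conditional(phi[perm], sigma2, cache_p),
               geofuse:::rho_conditional(phi, sigma2, cache),
               tolerance = 1e-8)

  fa <- geofuse:::alpha_conditional(Y, Z, phi, sigma2, nu2, 100)
  fa_p <- geofuse:::alpha_conditional(Y[perm], Z[perm, ], phi[perm], sigma2,
                                      nu2, 100)
  expect_equal(fa_p$mean, fa$mean, tolerance = 1e-10)
})
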