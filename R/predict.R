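# Shared kriging algebra: given the cached inverse correlation at one
# decay candidate, the cross-correlation C (N x m) and the
# prediction-set correlation Sigma_pred (N x N), return the weight
# matrix B = C Sigma_obs^-1 and the unit-variance conditional covariance
# V = Sigma_pred - B C'.
krige_system <- function(Sinv, C, Sigma_pred) {
  B <- C %*% Sinv
  V <- Sigma_pred - tcrossprod(B, C)
  list(B = B, V = (V + t(V)) / 2)
}

# Factor a conditional covariance for sampling, tolerating the exactly
# singular case (prediction at an observation site has zero variance).
# Tiny negative eigenvalues from rounding are clipped at zero; a warning
# is emitted if the deficit exceeds tolerance.
mvn_factor <- function(V, tol = 1e-8) {
  n <- nrow(V)
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(U)) return(t(U))
  e <- eigen(V, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -tol * max(abs(lam), 1))
    warning("conditional covariance has negative eigenvalue ",
            signif(min(lam), 3), "; clipped at zero")
  e$vectors %*% diag(sqrt(pmax(lam, 0)), n)
}

#' Krige the spatial random effects to new locations
#'
#' One draw (or the exact conditional moments) of the spatial effects at
#' prediction locations given the effects at the observation sites, for a
#' single posterior state: the conditional multivariate Gaussian with
#' mean `C Sigma_obs^-1 phi` and covariance
#' `sigma2 (Sigma_pred - C Sigma_obs^-1 C')`, equivalent to ordinary
#' kriging of a noiseless Gaussian field.
#'
#' @param phi Spatial effects at the m observation sites (one draw).
#' @param sigma2 Spatial variance of the same draw.
#' @param rho Decay value of the same draw (per km).
#' @param Sinv Cached m x m inverse correlation at `rho`.
#' @param cross_dist N x m matrix of prediction-to-observation distances
#'   in km.
#' @param pred_dist N x N distance matrix among prediction locations (km).
#' @param n_draws Number of conditional draws to return (0 for moments
#'   only).
#' @return `list(mean, cov, draws)` where `draws` is `n_draws` x N.
#' @export
krige_phi <- function(phi, sigma2, rho, Sinv, cross_dist, pred_dist,
                      n_draws = 1L) {
  C <- exp_correlation(cross_dist, rho)
  Sigma_pred <- exp_correlation(pred_dist, rho)
  ks <- krige_system(Sinv, C, Sigma_pred)
  mean <- drop(ks$B %*% phi)
  cov <- sigma2 * ks$V
  draws <- NULL
  if (n_draws > 0) {
    L <- mvn_factor(ks$V)
    N <- length(mean)
    draws <- matrix(mean, n_draws, N, byrow = TRUE) +
      sqrt(sigma2) * t(L %*% matrix(stats::rnorm(N * n_draws), N, n_draws))
  }
  list(mean = mean, cov = cov, draws = draws)
}

#' Draw predicted log concentrations from kriged effects
#'
#' Second step of the two-step prediction: adds the covariate mean and
#' the nugget noise to a kriged spatial-effect draw, giving
#' `Y* ~ N(Z* alpha + phi*, nu2 sigma2)` per location.
#'
#' @param alpha Coefficient draw.
#' @param phi_star Kriged spatial effects at the prediction locations.
#' @param Zstar Design matrix at the prediction locations (built with the
#'   training fit's centring constants and factor levels).
#' @param sigma2,nu2 Variance draws.
#' @return A log-scale prediction draw (length N).
#' @export
predict_y <- function(alpha, phi_star, Zstar, sigma2, nu2) {
  N <- nrow(Zstar)
  drop(Zstar %*% alpha) + phi_star +
    stats::rnorm(N, sd = sqrt(nu2 * sigma2))
}

#' Summarise posterior prediction draws
#'
#' Per-location posterior median, standard deviation and central interval
#' on the log scale; the median and interval endpoints are exponentiated
#' to ug/m3 (so the concentration-scale median is exactly the exponential
#' of the log-scale median). The standard deviation is reported on the
#' log scale, the model's "standard error" of prediction.
#'
#' @param draws M x N matrix of log-scale prediction draws.
#' @param level Central interval probability (default 0.95).
#' @return A data frame with columns `median_log`, `sd_log`, `lo_log`,
#'   `hi_log`, `median_ugm3`, `lo_ugm3`, `hi_ugm3`.
#' @export
summarize_predictions <- function(draws, level = 0.95) {
  draws <- as.matrix(draws)
  a <- (1 - level) / 2
  q <- apply(draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a))
  out <- data.frame(
    median_log = q[2, ], sd_log = apply(draws, 2, stats::sd),
    lo_log = q[1, ], hi_log = q[3, ]
  )
  out$median_ugm3 <- exp(out$median_log)
  out$lo_ugm3 <- exp(out$lo_log)
  out$hi_ugm3 <- exp(out$hi_log)
  rownames(out) <- NULL
  out
}

# Core posterior-predictive engine: M x N matrix of log-scale draws at
# arbitrary locations. Draws are grouped by their decay index so the
# kriging weights and the conditional covariance factor are computed once
# per candidate per batch. Batching over locations keeps the N x N
# conditional covariance bounded; independent sampling across batches is
# valid because the conditioning is only on phi at the observed sites.
predictive_draws_mcmc <- function(object, coords_m, Zstar,
                                  include_nugget = TRUE, batch_size = 250L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$fit
  M <- s$n_keep
  N <- nrow(Zstar)
  obs_km <- object$coords_km
  new_km <- as.matrix(coords_m) / 1000
  draws <- matrix(NA_real_, M, N)
  mean_part <- tcrossprod(s$alpha, Zstar)       # M x N covariate mean
  sd_nugget <- sqrt(s$nu2 * s$sigma2)

  batches <- split(seq_len(N), ceiling(seq_len(N) / batch_size))
  for (idx in batches) {
    nb <- length(idx)
    dx <- outer(new_km[idx, 1], obs_km[, 1], "-")
    dy <- outer(new_km[idx, 2], obs_km[, 2], "-")
    cross <- sqrt(dx^2 + dy^2)
    pd <- as.matrix(stats::dist(new_km[idx, , drop = FALSE]))
    for (k in sort(unique(s$rho_index))) {
      rows <- which(s$rho_index == k)
      rho_k <- s$rho_grid[k]
      ks <- krige_system(object$cache$Sinv[[k]],
                         exp_correlation(cross, rho_k),
                         exp_correlation(pd, rho_k))
      L <- mvn_factor(ks$V)
      means <- s$phi[rows, , drop = FALSE] %*% t(ks$B)   # |rows| x nb
      z <- matrix(stats::rnorm(nb * length(rows)), nb)
      phi_star <- means + sqrt(s$sigma2[rows]) * t(L %*% z)
      draws[rows, idx] <- mean_part[rows, idx] + phi_star
      if (include_nugget)
        draws[rows, idx] <- draws[rows, idx] +
          sd_nugget[rows] * matrix(stats::rnorm(length(rows) * nb),
                                   length(rows), nb)
    }
  }
  draws
}

#' Predict from a fusion fit at new locations
#'
#' Two-step Bayesian prediction for MCMC fits: for every retained
#' posterior draw the spatial effects are kriged to the new locations
#' (conditional multivariate Gaussian) and the observation model adds the
#' covariate mean and nugget noise; the draws are then summarised per
#' location. REML fits use plug-in universal kriging with the estimates
#' treated as fixed and known; OLS fits use iid Gaussian prediction
#' intervals.
#'
#' @param object A [fit_fusion()] object.
#' @param newdata A site-like table: coordinates plus whatever covariate
#'   columns the fitted spec requires (`pcm_no2_ugm3`, `source`,
#'   `environment`).
#' @param level Central prediction-interval probability.
#' @param include_nugget Include the nugget in the predictive variance
#'   (TRUE predicts a new observation; FALSE the latent surface).
#' @param batch_size Locations per kriging batch (MCMC fits).
#' @param seed Optional RNG seed for the predictive draws.
#' @param ... Unused.
#' @return [summarize_predictions()] output, one row per location, with
#'   the draws attached as attribute `draws` for MCMC fits.
#' @export
predict.fusion_fit <- function(object, newdata, level = 0.95,
                               include_nugget = TRUE, batch_size = 250L,
                               seed = NULL, ...) {
  Zstar <- build_design_matrix(newdata, object$spec, template = object$Z)
  coords_m <- as.matrix(newdata[, c("easting_m", "northing_m")])

  if (object$method == "mcmc") {
    draws <- predictive_draws_mcmc(object, coords_m, Zstar,
                                   include_nugget = include_nugget,
                                   batch_size = batch_size, seed = seed)
    out <- summarize_predictions(draws, level)
    attr(out, "draws") <- draws
    return(out)
  }

  if (object$method == "reml") {
    f <- object$fit
    obs_km <- object$coords_km
    new_km <- coords_m / 1000
    dx <- outer(new_km[, 1], obs_km[, 1], "-")
    dy <- outer(new_km[, 2], obs_km[, 2], "-")
    C <- exp_correlation(sqrt(dx^2 + dy^2), f$rho)
    B <- C %*% f$Vinv
    mean <- drop(Zstar %*% f$alpha) + drop(B %*% f$resid)
    nug <- if (include_nugget) f$nu2 else 0
    v <- pmax(f$sigma2 * (1 + nug - rowSums(B * C)), 0)
    zq <- stats::qnorm(1 - (1 - level) / 2)
    out <- data.frame(median_log = mean, sd_log = sqrt(v),
                      lo_log = mean - zq * sqrt(v),
                      hi_log = mean + zq * sqrt(v))
  } else {
    nd <- as.data.frame(Zstar, check.names = FALSE)
    pr <- stats::predict(object$fit$lm, newdata = nd,
                         interval = if (include_nugget) "prediction" else "confidence",
                         level = level, se.fit = TRUE)
    sd_pred <- sqrt(pr$se.fit^2 +
                    if (include_nugget) pr$residual.scale^2 else 0)
    out <- data.frame(median_log = unname(pr$fit[, "fit"]),
                      sd_log = unname(sd_pred),
                      lo_log = unname(pr$fit[, "lwr"]),
                      hi_log = unname(pr$fit[, "upr"]))
  }
  out$median_ugm3 <- exp(out$median_log)
  out$lo_ugm3 <- exp(out$lo_log)
  out$hi_ugm3 <- exp(out$hi_log)
  rownames(out) <- NULL
  out
}

#' Predict the full concentration surface on a regular grid
#'
#' Applies the fitted model to every cell of a grid table. Following
#' exposure-assessment convention, each cell's environment is forced to
#' urban background where the urban flag is set and rural otherwise
#' (grid-cell averages are not representative of kerbside/roadside
#' exposure), and the source indicator, when in the spec, is set to its
#' reference level (tube).
#'
#' @param object A [fit_fusion()] object.
#' @param grid A grid table (see [read_grid()]).
#' @param ... Passed on to [predict.fusion_fit()].
#' @return One summary row per cell, with `cell_id` and `urban` prepended.
#' @export
predict_grid <- function(object, grid, ...) {
  if (is.null(grid$pcm_no2_ugm3) || any(!is.finite(grid$pcm_no2_ugm3)))
    stop("grid must carry finite pcm_no2_ugm3 values in every cell")
  if (is.null(grid$urban)) stop("grid must carry an urban flag")
  newdata <- data.frame(
    easting_m = grid$easting_m, northing_m = grid$northing_m,
    pcm_no2_ugm3 = grid$pcm_no2_ugm3,
    source = object$spec$ref_source,
    environment = ifelse(grid$urban, "urban_background", "rural"),
    stringsAsFactors = FALSE
  )
  out <- predict(object, newdata, ...)
  cbind(data.frame(cell_id = grid$cell_id, urban = grid$urban,
                   stringsAsFactors = FALSE), out)
}
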