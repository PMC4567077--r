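#' Fit the geostatistical fusion model to a site table
#'
#' The central fitting function. Builds the design matrix from a
#' [covariate_spec()], jitters co-located coordinates, precomputes the
#' correlation cache over the decay candidates, and fits by one of three
#' methods: `"mcmc"` (the Bayesian model: Gibbs/Metropolis sampling of
#' `alpha, phi, sigma2, nu2, rho`), `"reml"` (restricted maximum
#' likelihood with plug-in predictions) or `"ols"` (ordinary least
#' squares, ignoring spatial autocorrelation). All modelling is on the
#' natural-log concentration scale.
#'
#' @param sites A site table with columns `easting_m`, `northing_m`,
#'   `source`, `environment`, `pcm_no2_ugm3`, `no2_ugm3` (see
#'   [read_sites()]).
#' @param spec A [covariate_spec()].
#' @param method `"mcmc"`, `"reml"` or `"ols"`.
#' @param priors A [prior_spec()] (MCMC only).
#' @param n_burn,n_keep Chain lengths (MCMC only).
#' @param seed RNG seed (MCMC only).
#' @param rho_grid Decay candidates; defaults to [default_rho_grid()] of
#'   the site distance matrix (overridden by `priors$rho_grid` if set).
#' @param verbose Progress messages.
#' @return An object of class `fusion_fit` with components `method`,
#'   `fit` (the method-specific fit), `Y` (log observations), `Z` (design
#'   matrix), `coords_km` (jittered coordinates in km), `cache`, `sites`,
#'   `spec` and `n_factorizations`. Supports `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `plot` and `predict`.
#' @examples
#' cfg <- synthetic_config(n_tubes = 40, n_monitors = 6, n_colocated = 3,
#'                         seed = 7)
#' grid <- generate_grid(cfg)
#' sites <- generate_sites(cfg, grid)
#' spec <- covariate_spec(log_modelled = TRUE, source = TRUE,
#'                        environment = TRUE)
#' sites <- simulate_observations(sites, spec, cfg$true_params, seed = 7)
#' fit <- fit_fusion(sites, spec, n_burn = 200, n_keep = 200, seed = 1)
#' coef(fit)
#' @export
fit_fusion <- function(sites, spec = covariate_spec(),
                       method = c("mcmc", "reml", "ols"),
                       priors = prior_spec(), n_burn = 2000L,
                       n_keep = 1000L, seed = NULL, rho_grid = NULL,
                       verbose = FALSE) {
  method <- match.arg(method)
  conc <- sites$no2_ugm3
  if (any(!is.finite(conc) | conc <= 0))
    stop("all observed concentrations must be finite and strictly positive")
  Y <- log(conc)
  Z <- build_design_matrix(sites, spec)

  coords <- jitter_duplicates(as.matrix(sites[, c("easting_m", "northing_m")]))
  cache <- NULL
  if (method != "ols") {
    D <- distance_matrix(coords)
    if (is.null(rho_grid)) rho_grid <- priors$rho_grid
    if (is.null(rho_grid)) rho_grid <- default_rho_grid(D)
    cache <- build_correlation_cache(D, rho_grid)
  }

  fit <- switch(method,
    mcmc = run_mcmc(Y, Z, cache, priors, n_burn = n_burn, n_keep = n_keep,
                    seed = seed, verbose = verbose),
    reml = reml_fit(Y, Z, cache),
    ols = ols_fit(Y, Z))

  structure(list(
    method = method, fit = fit, Y = Y, Z = Z,
    coords_km = coords / 1000, cache = cache, sites = sites, spec = spec,
    n_factorizations = if (is.null(cache)) 0L else cache$n_factorizations
  ), class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat("Geostatistical fusion model fit (", x$method, "), m = ",
      length(x$Y), " sites, p = ", ncol(x$Z), " coefficients\n", sep = "")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.fusion_fit <- function(object, ...) {
  switch(object$method,
    mcmc = apply(object$fit$alpha, 2, stats::median),
    reml = object$fit$alpha,
    ols = object$fit$alpha)
}

#' Posterior / estimate summary of a fusion fit
#'
#' For an MCMC fit: posterior medians and central 95% credible intervals
#' of the coefficients and of `sigma2`, `nu2` and `rho`, the
#' Metropolis acceptance rate of the `nu2` step, and Geweke-style
#' stationarity z-scores. For REML/OLS: point estimates.
#'
#' @param object A `fusion_fit`.
#' @param ... Unused.
#' @export
summary.fusion_fit <- function(object, ...) {
  if (object$method == "mcmc") {
    s <- object$fit
    draws <- cbind(s$alpha, sigma2 = s$sigma2, nu2 = s$nu2, rho = s$rho)
    tab <- t(apply(draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
    colnames(tab) <- c("median", "lo95", "hi95")
    out <- list(method = "mcmc", table = tab, acc_rate = s$acc_rate,
                convergence = s$convergence, n_keep = s$n_keep,
                n_factorizations = object$n_factorizations)
  } else if (object$method == "reml") {
    f <- object$fit
    se <- sqrt(diag(f$alpha_cov))
    tab <- cbind(estimate = c(f$alpha, sigma2 = f$sigma2, nu2 = f$nu2,
                              rho = f$rho),
                 se = c(se, NA, NA, NA))
    out <- list(method = "reml", table = tab, logrestlik = f$logrestlik)
  } else {
    out <- list(method = "ols", table = summary(object$fit$lm)$coefficients)
  }
  structure(out, class = "summary.fusion_fit")
}

#' @export
print.summary.fusion_fit <- function(x, ...) {
  cat("Fusion model (", x$method, ")\n", sep = "")
  print(round(x$table, 4))
  if (x$method == "mcmc") {
    cat("nu2 MH acceptance rate:", round(x$acc_rate, 3),
        "| correlation factorizations:", x$n_factorizations, "\n")
    z <- x$convergence
    cat("Geweke z (sigma2, nu2):", paste(round(z, 2), collapse = ", "),
        if (any(abs(z) > 2, na.rm = TRUE)) "  [check trace plots]" else "", "\n")
  }
  invisible(x)
}

#' @export
fitted.fusion_fit <- function(object, ...) {
  switch(object$method,
    mcmc = {
      mu <- object$Z %*% t(object$fit$alpha) + t(object$fit$phi)
      apply(mu, 1, stats::median)
    },
    reml = {
      f <- object$fit   # E[phi | Y] = resid - nu2 * Vinv %*% resid
      drop(object$Z %*% f$alpha) + f$resid - f$nu2 * drop(f$Vinv %*% f$resid)
    },
    ols = unname(stats::fitted(object$fit$lm)))
}

#' @export
residuals.fusion_fit <- function(object, ...) {
  object$Y - fitted(object)
}

#' Diagnostic plots for a fusion fit
#'
#' MCMC fits: trace plots of `sigma2`, `nu2`, `rho` and the first
#' non-intercept coefficient. REML/OLS: residuals against fitted values.
#'
#' @param x A `fusion_fit`.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.fusion_fit <- function(x, ...) {
  if (x$method == "mcmc") {
    s <- x$fit
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(s$sigma2, type = "l", ylab = "sigma2", xlab = "iteration", ...)
    graphics::plot(s$nu2, type = "l", ylab = "nu2", xlab = "iteration", ...)
    graphics::plot(s$rho, type = "l", ylab = "rho", xlab = "iteration", ...)
    j <- min(2L, ncol(s$alpha))
    graphics::plot(s$alpha[, j], type = "l", ylab = colnames(s$alpha)[j],
                   xlab = "iteration", ...)
  } else {
    graphics::plot(fitted(x), residuals(x), xlab = "fitted (log scale)",
                   ylab = "residual", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
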