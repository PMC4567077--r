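#' Prior specification for the Bayesian fusion model
#'
#' Weakly informative defaults: independent N(0, 1000) on each regression
#' coefficient, InvGamma(0.001, 0.001) on the spatial variance, uniform
#' (0,1) on the noise-to-signal ratio, and a discrete uniform prior over
#' the decay candidates (supplied at fit time, see [default_rho_grid()]).
#'
#' @param alpha_prior_var Prior variance of each coefficient.
#' @param ig_a,ig_b Inverse-gamma shape and scale for `sigma2`.
#' @param rho_grid Optional decay candidates; when `NULL` the fit derives
#'   them from the data's distance matrix.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(alpha_prior_var = 1000, ig_a = 0.001, ig_b = 0.001,
                       rho_grid = NULL) {
  if (alpha_prior_var <= 0 || ig_a <= 0 || ig_b <= 0)
    stop("prior hyperparameters must be positive")
  if (!is.null(rho_grid) && length(rho_grid) < 1L)
    stop("rho_grid must be nonempty when supplied")
  structure(list(alpha_prior_var = alpha_prior_var, ig_a = ig_a,
                 ig_b = ig_b, rho_grid = rho_grid),
            class = "prior_spec")
}

#' Run the Gibbs/Metropolis MCMC for the fusion model
#'
#' Systematic-scan sampler: per iteration `alpha` (Gibbs), `phi` (Gibbs),
#' `sigma2` (Gibbs), `nu2` (Metropolis-Hastings on the logit scale, step
#' size adapted during burn-in only towards 20-50% acceptance, frozen
#' afterwards), `rho` (exact discrete Gibbs over the cached candidates).
#' All correlation-matrix factorisations happen once, in the cache;
#' regardless of chain length exactly `r` are performed per fitted
#' dataset.
#'
#' @param Y Log-scale observation vector.
#' @param Z Design matrix (see [build_design_matrix()]).
#' @param cache A [build_correlation_cache()] object for the same sites.
#' @param priors A [prior_spec()].
#' @param n_burn Burn-in iterations (discarded).
#' @param n_keep Retained posterior samples.
#' @param seed Integer RNG seed; fixes the whole chain.
#' @param nu2_step Initial logit-scale proposal standard deviation.
#' @param verbose Print progress every 1000 iterations.
#' @return An object of class `fusion_mcmc`: matrices `alpha`
#'   (`n_keep` x p) and `phi` (`n_keep` x m), vectors `sigma2`, `nu2`,
#'   `rho_index`, `rho`, plus the acceptance rate of the `nu2` step over
#'   the retained phase, the frozen step size, the factorisation count
#'   and Geweke-style convergence z-scores for the variance parameters.
#' @export
run_mcmc <- function(Y, Z, cache, priors = prior_spec(), n_burn = 2000L,
                     n_keep = 1000L, seed = NULL, nu2_step = 1,
                     verbose = FALSE) {
  stopifnot(inherits(cache, "correlation_cache"))
  m <- length(Y)
  if (nrow(Z) != m || cache$m != m) stop("Y, Z and cache dimensions disagree")
  if (n_keep < 1L) stop("n_keep must be positive")
  if (!is.null(seed)) set.seed(seed)

  p <- ncol(Z)
  # Initial values: OLS coefficients, zero spatial effects, an even split
  # of the residual variance, the middle decay candidate.
  alpha <- qr.coef(qr(Z), Y)
  alpha[is.na(alpha)] <- 0
  resid0 <- Y - drop(Z %*% alpha)
  sigma2 <- max(stats::var(resid0), 1e-6)
  nu2 <- 0.3
  phi <- rep(0, m)
  k <- max(1L, cache$r %/% 2L)

  n_iter <- n_burn + n_keep
  keep_alpha <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(Z)))
  keep_phi <- matrix(NA_real_, n_keep, m)
  keep_sigma2 <- keep_nu2 <- numeric(n_keep)
  keep_rho_index <- integer(n_keep)

  acc_window <- 0L; acc_kept <- 0L; window_n <- 0L
  step <- nu2_step
  ZtZ <- crossprod(Z)

  for (it in seq_len(n_iter)) {
    alpha <- sample_alpha(Y, Z, phi, sigma2, nu2, priors$alpha_prior_var,
                          ZtZ = ZtZ)
    Zalpha <- drop(Z %*% alpha)
    phi <- sample_phi(Y, Z, alpha, sigma2, nu2, cache$Sinv[[k]],
                      Zalpha = Zalpha)
    ss <- sum((Y - Zalpha - phi)^2)
    qf_all <- quad_forms_all(cache, phi)
    sigma2 <- sample_sigma2(Y, Z, alpha, phi, nu2, qf_all[k],
                            priors$ig_a, priors$ig_b, ss = ss)
    if (!is.finite(sigma2) || sigma2 > 1e8)
      stop("MCMC divergence: sigma2 = ", sigma2, " at iteration ", it,
           " (nu2 = ", signif(nu2, 4), ", rho index = ", k, ")")
    upd <- sample_nu2(Y, Z, alpha, phi, sigma2, nu2, step, ss = ss)
    nu2 <- upd$nu2
    k <- sample_rho(phi, sigma2, cache, qf_all)

    if (it <= n_burn) {
      acc_window <- acc_window + upd$accepted
      window_n <- window_n + 1L
      if (window_n == 50L) {          # adapt during burn-in only
        rate <- acc_window / 50
        if (rate < 0.2) step <- step * 0.7
        if (rate > 0.5) step <- step * 1.4
        acc_window <- 0L; window_n <- 0L
      }
    } else {
      j <- it - n_burn
      acc_kept <- acc_kept + upd$accepted
      keep_alpha[j, ] <- alpha
      keep_phi[j, ] <- phi
      keep_sigma2[j] <- sigma2
      keep_nu2[j] <- nu2
      keep_rho_index[j] <- k
    }
    if (verbose && it %% 1000L == 0L)
      message("iteration ", it, "/", n_iter)
  }

  structure(list(
    alpha = keep_alpha, phi = keep_phi, sigma2 = keep_sigma2,
    nu2 = keep_nu2, rho_index = keep_rho_index,
    rho = cache$rho_grid[keep_rho_index],
    rho_grid = cache$rho_grid,
    acc_rate = acc_kept / n_keep, nu2_step = step,
    n_burn = n_burn, n_keep = n_keep, seed = seed,
    n_factorizations = cache$n_factorizations,
    convergence = c(sigma2 = geweke_z(keep_sigma2),
                    nu2 = geweke_z(keep_nu2))
  ), class = "fusion_mcmc")
}

# Geweke-style stationarity diagnostic: z-score comparing the mean of the
# first 10% of the retained chain with the last 50%, with variances
# estimated from each segment's autoregressive spectrum at frequency zero.
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 40L) return(NA_real_)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[(n - floor(frac2 * n) + 1L):n]
  s0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    fit <- tryCatch(stats::ar(v, aic = TRUE,
                              order.max = min(20L, length(v) %/% 4L)),
                    error = function(e) NULL)
    if (is.null(fit)) return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  se <- sqrt(s0(a) / length(a) + s0(b) / length(b))
  if (se == 0) return(0)
  (mean(a) - mean(b)) / se
}
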