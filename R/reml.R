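#' Restricted maximum likelihood fit of the spatial model
#'
#' Likelihood-based comparator to the Bayesian fit: the marginal model
#' `Y ~ N(Z alpha, sigma2 [Sigma(rho) + nu2 I])` is estimated by
#' maximising the restricted log-likelihood over `nu2` (1-D optimisation
#' on the log scale) profiled over the discrete decay candidates, with
#' `sigma2` profiled out in closed form and `alpha` the GLS estimate at
#' the optimum. Predictions from this fit treat the estimates as fixed
#' and known (plug-in kriging), which is the stated contrast with the
#' Bayesian fit's full propagation of parameter uncertainty.
#'
#' @param Y Log-scale observation vector.
#' @param Z Design matrix.
#' @param cache A [build_correlation_cache()] object for the same sites.
#' @param nu2_interval Search interval for `nu2` (default `[1e-6, 5]`;
#'   REML is allowed to push the nugget ratio above 1).
#' @return An object of class `fusion_reml`: `alpha` (GLS estimates),
#'   `sigma2`, `nu2`, `rho`, `rho_index`, `logrestlik`, `Vinv`
#'   (inverse of `Sigma(rho) + nu2 I`), `resid` (GLS residuals) and
#'   `alpha_cov` (plug-in covariance of the coefficient estimates).
#' @export
reml_fit <- function(Y, Z, cache, nu2_interval = c(1e-6, 5)) {
  stopifnot(inherits(cache, "correlation_cache"))
  m <- length(Y); p <- ncol(Z)
  if (m <= p) stop("need more sites than coefficients for REML")

  # Restricted log-likelihood for V = exp(-rho D) + nu2 I, sigma2 profiled.
  rll <- function(nu2, S) {
    V <- S
    diag(V) <- diag(V) + nu2
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(list(value = -Inf))
    logdetV <- 2 * sum(log(diag(U)))
    Vi_Z <- backsolve(U, backsolve(U, Z, transpose = TRUE))
    Vi_Y <- backsolve(U, backsolve(U, Y, transpose = TRUE))
    ZtViZ <- crossprod(Z, Vi_Z)
    Uz <- tryCatch(chol(ZtViZ), error = function(e) NULL)
    if (is.null(Uz)) return(list(value = -Inf))
    alpha <- backsolve(Uz, backsolve(Uz, crossprod(Z, Vi_Y), transpose = TRUE))
    r <- Y - drop(Z %*% alpha)
    Vi_r <- backsolve(U, backsolve(U, r, transpose = TRUE))
    sigma2 <- sum(r * Vi_r) / (m - p)
    value <- -0.5 * ((m - p) * log(sigma2) + logdetV +
                     2 * sum(log(diag(Uz))) + (m - p))
    list(value = value, alpha = drop(alpha), sigma2 = sigma2, U = U,
         ZtViZ_chol = Uz, resid = r)
  }

  best <- NULL
  for (k in seq_len(cache$r)) {
    S <- exp(-cache$rho_grid[k] * cache$D)
    opt <- stats::optimize(function(lv) rll(exp(lv), S)$value,
                           interval = log(nu2_interval), maximum = TRUE)
    if (is.null(best) || opt$objective > best$value) {
      fit_k <- rll(exp(opt$maximum), S)
      if (is.finite(fit_k$value))
        best <- c(fit_k, list(nu2 = exp(opt$maximum), rho_index = k))
    }
  }
  if (is.null(best)) stop("REML optimisation failed for every decay candidate")

  U <- best$U
  Vinv <- chol2inv(U)
  alpha_cov <- best$sigma2 * chol2inv(best$ZtViZ_chol)
  structure(list(
    alpha = stats::setNames(best$alpha, colnames(Z)),
    sigma2 = best$sigma2, nu2 = best$nu2,
    rho = cache$rho_grid[best$rho_index], rho_index = best$rho_index,
    logrestlik = best$value, Vinv = Vinv, resid = best$resid,
    alpha_cov = alpha_cov, rho_grid = cache$rho_grid
  ), class = "fusion_reml")
}

# Profiled restricted log-likelihood at arbitrary (nu2, rho); used by the
# optimality checks.
reml_loglik_at <- function(Y, Z, cache, nu2, rho_index) {
  m <- length(Y); p <- ncol(Z)
  V <- exp(-cache$rho_grid[rho_index] * cache$D)
  diag(V) <- diag(V) + nu2
  U <- chol(V)
  Vi_Z <- backsolve(U, backsolve(U, Z, transpose = TRUE))
  Vi_Y <- backsolve(U, backsolve(U, Y, transpose = TRUE))
  Uz <- chol(crossprod(Z, Vi_Z))
  alpha <- backsolve(Uz, backsolve(Uz, crossprod(Z, Vi_Y), transpose = TRUE))
  r <- Y - drop(Z %*% alpha)
  sigma2 <- sum(r * backsolve(U, backsolve(U, r, transpose = TRUE))) / (m - p)
  -0.5 * ((m - p) * log(sigma2) + 2 * sum(log(diag(U))) +
          2 * sum(log(diag(Uz))) + (m - p))
}

#' Ordinary least squares fit ignoring spatial autocorrelation
#'
#' The naive comparator: `lm()` on the log scale with iid Gaussian
#' errors. Predictions use standard `predict.lm()` prediction intervals.
#'
#' @param Y Log-scale observation vector.
#' @param Z Design matrix (full column rank).
#' @return An object of class `fusion_ols` wrapping the `lm` fit.
#' @export
ols_fit <- function(Y, Z) {
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("design matrix is rank deficient (rank ", qrz$rank, " < ", ncol(Z), ")")
  dat <- as.data.frame(Z, check.names = FALSE)
  dat$.y <- Y
  lmfit <- stats::lm(.y ~ 0 + ., data = dat)
  structure(list(lm = lmfit,
                 alpha = stats::setNames(stats::coef(lmfit), colnames(Z)),
                 sigma2 = summary(lmfit)$sigma^2),
            class = "fusion_ols")
}
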