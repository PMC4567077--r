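# Full-conditional updates of the Gibbs/Metropolis sampler. Each update
# conditions on the current values of the remaining parameters in
# Theta = (alpha, phi, sigma2, nu2, rho). Observation model:
#   Y ~ N(Z alpha + phi, nu2 sigma2 I),  phi ~ N(0, sigma2 Sigma(rho)),
# with priors alpha ~ N(0, prior_var I), sigma2 ~ InvGamma(a, b),
# nu2 ~ U(0, 1), rho ~ DiscreteUniform(rho_1, ..., rho_r).

# Conditional moments of alpha (conjugate Gaussian regression update).
alpha_conditional <- function(Y, Z, phi, sigma2, nu2, prior_var,
                              ZtZ = NULL) {
  tau <- nu2 * sigma2
  if (is.null(ZtZ)) ZtZ <- crossprod(Z)
  A <- ZtZ / tau
  diag(A) <- diag(A) + 1 / prior_var
  U <- chol(A)
  b <- crossprod(Z, Y - phi) / tau
  mean <- backsolve(U, backsolve(U, b, transpose = TRUE))
  list(mean = drop(mean), chol_prec = U)
}

#' Gibbs update of the regression coefficients
#'
#' Exact draw from the Gaussian full conditional of `alpha` given the
#' de-trended data `Y - phi`, observation variance `nu2 * sigma2`, and the
#' zero-mean diagonal Gaussian prior with variance `prior_var`.
#'
#' @param Y Log-scale observation vector.
#' @param Z Design matrix.
#' @param phi Current spatial effects.
#' @param sigma2,nu2 Current variance parameters.
#' @param prior_var Prior variance of each coefficient.
#' @param ZtZ Optional precomputed `crossprod(Z)`.
#' @return A coefficient draw (numeric p-vector).
#' @keywords internal
#' @export
sample_alpha <- function(Y, Z, phi, sigma2, nu2, prior_var = 1000,
                         ZtZ = NULL) {
  fc <- alpha_conditional(Y, Z, phi, sigma2, nu2, prior_var, ZtZ)
  drop(fc$mean + backsolve(fc$chol_prec, stats::rnorm(ncol(Z))))
}

# Conditional moments of phi: precision sigma2^-1 (Sinv + I/nu2),
# mean = Prec^-1 (Y - Z alpha) / (nu2 sigma2).
phi_conditional <- function(Y, Z, alpha, sigma2, nu2, Sinv,
                            Zalpha = NULL) {
  if (is.null(Zalpha)) Zalpha <- drop(Z %*% alpha)
  m <- nrow(Sinv)
  P <- Sinv / sigma2
  dix <- seq.int(1L, by = m + 1L, length.out = m)
  P[dix] <- P[dix] + 1 / (nu2 * sigma2)
  U <- chol(P)
  b <- (Y - Zalpha) / (nu2 * sigma2)
  mean <- backsolve(U, backsolve(U, b, transpose = TRUE))
  list(mean = drop(mean), chol_prec = U)
}

#' Gibbs update of the spatial random effects
#'
#' Exact multivariate Gaussian full-conditional draw of `phi`, with
#' precision `sigma2^-1 (Sigma(rho)^-1 + nu2^-1 I)` and mean solving that
#' precision against `(Y - Z alpha) / (nu2 sigma2)`.
#'
#' @inheritParams sample_alpha
#' @param alpha Current regression coefficients.
#' @param Sinv Cached inverse correlation matrix at the current decay
#'   candidate.
#' @param Zalpha Optional precomputed `Z %*% alpha`.
#' @return A spatial-effect draw (numeric m-vector).
#' @keywords internal
#' @export
sample_phi <- function(Y, Z, alpha, sigma2, nu2, Sinv, Zalpha = NULL) {
  fc <- phi_conditional(Y, Z, alpha, sigma2, nu2, Sinv, Zalpha)
  drop(fc$mean + backsolve(fc$chol_prec, stats::rnorm(length(Y))))
}

# Shape/scale of the inverse-gamma full conditional of sigma2. Both the
# spatial effects (variance sigma2 Sigma) and the nugget (variance
# nu2 sigma2) scale with sigma2, so each contributes m/2 to the shape.
sigma2_conditional <- function(Y, Z, alpha, phi, nu2, qf, ig_a, ig_b,
                               ss = NULL) {
  m <- length(Y)
  if (is.null(ss)) ss <- sum((Y - drop(Z %*% alpha) - phi)^2)
  list(shape = ig_a + m, scale = ig_b + 0.5 * (qf + ss / nu2))
}

#' Gibbs update of the spatial variance
#'
#' Exact inverse-gamma draw with shape `a + m` and scale
#' `b + (phi' Sigma^-1 phi + ||Y - Z alpha - phi||^2 / nu2) / 2`.
#'
#' @inheritParams sample_phi
#' @param phi Current spatial effects.
#' @param qf Quadratic form `phi' Sigma(rho)^-1 phi` at the current decay
#'   candidate (pass `drop(phi %*% Sinv %*% phi)`).
#' @param ig_a,ig_b Inverse-gamma prior shape and scale.
#' @param ss Optional precomputed residual sum of squares
#'   `||Y - Z alpha - phi||^2`.
#' @return A positive scalar draw.
#' @keywords internal
#' @export
sample_sigma2 <- function(Y, Z, alpha, phi, nu2, qf, ig_a = 0.001,
                          ig_b = 0.001, ss = NULL) {
  fc <- sigma2_conditional(Y, Z, alpha, phi, nu2, qf, ig_a, ig_b, ss)
  1 / stats::rgamma(1, shape = fc$shape, rate = fc$scale)
}

# Log full conditional of nu2 on (0,1) up to a constant.
nu2_log_conditional <- function(nu2, ss, m, sigma2) {
  -m / 2 * log(nu2 * sigma2) - ss / (2 * nu2 * sigma2)
}

#' Metropolis-Hastings update of the noise-to-signal ratio
#'
#' Random-walk proposal on the logit scale targeting the full conditional
#' of `nu2` (uniform prior on (0,1)); the logit Jacobian `nu2 (1 - nu2)`
#' is included in the acceptance ratio. Proposing the current value is
#' always accepted.
#'
#' @inheritParams sample_sigma2
#' @param nu2 Current value in (0, 1).
#' @param step Random-walk standard deviation on the logit scale.
#' @param ss Optional precomputed residual sum of squares.
#' @return `list(nu2 = new value, accepted = TRUE/FALSE)`.
#' @keywords internal
#' @export
sample_nu2 <- function(Y, Z, alpha, phi, sigma2, nu2, step = 1, ss = NULL) {
  m <- length(Y)
  if (is.null(ss)) ss <- sum((Y - drop(Z %*% alpha) - phi)^2)
  theta <- stats::qlogis(nu2)
  theta_new <- theta + stats::rnorm(1, sd = step)
  nu2_new <- stats::plogis(theta_new)
  log_ratio <- nu2_log_conditional(nu2_new, ss, m, sigma2) -
    nu2_log_conditional(nu2, ss, m, sigma2) +
    log(nu2_new * (1 - nu2_new)) - log(nu2 * (1 - nu2))
  accepted <- is.finite(log_ratio) && log(stats::runif(1)) < log_ratio
  list(nu2 = if (accepted) nu2_new else nu2, accepted = accepted)
}

# Normalised discrete full-conditional probabilities of the decay index.
rho_conditional <- function(phi, sigma2, cache, qf_all = NULL) {
  if (is.null(qf_all)) qf_all <- quad_forms_all(cache, phi)
  logp <- -0.5 * cache$logdet - qf_all / (2 * sigma2)
  mx <- max(logp)
  if (!is.finite(mx)) stop("all decay candidates have zero conditional probability")
  p <- exp(logp - mx)
  p / sum(p)
}

#' Gibbs update of the spatial decay parameter
#'
#' Exact draw from the discrete full conditional over the cached decay
#' candidates, `p(rho_k | phi, sigma2) proportional to
#' exp(-logdet(Sigma_k)/2 - phi' Sigma_k^-1 phi / (2 sigma2))`, evaluated
#' with a log-sum-exp guard. Uniform prior mass cancels.
#'
#' @param phi Current spatial effects.
#' @param sigma2 Current spatial variance.
#' @param cache A [build_correlation_cache()] object.
#' @param qf_all Optional precomputed vector of quadratic forms
#'   `phi' Sigma_k^-1 phi` (one per candidate).
#' @return The sampled candidate index in `1..r`.
#' @keywords internal
#' @export
sample_rho <- function(phi, sigma2, cache, qf_all = NULL) {
  p <- rho_conditional(phi, sigma2, cache, qf_all)
  sample.int(cache$r, 1L, prob = p)
}
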