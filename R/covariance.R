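#' Pairwise distance matrix in kilometres
#'
#' Computes the symmetric Euclidean distance matrix between site
#' coordinates. Coordinates are supplied in metres (easting/northing) and
#' converted to kilometres before distances are taken: the spatial decay
#' parameter of the fusion model is expressed per kilometre throughout the
#' package.
#'
#' @param coords A two-column matrix or data frame of easting/northing in
#'   metres.
#' @return An m x m symmetric matrix of distances in km with zero diagonal.
#' @export
distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (easting, northing)")
  if (nrow(coords) < 2L) stop("need at least two sites to form a distance matrix")
  storage.mode(coords) <- "double"
  D <- as.matrix(stats::dist(coords / 1000))
  dimnames(D) <- NULL
  D
}

#' Deterministically jitter duplicated coordinates
#'
#' Co-located monitor/tube pairs share exact coordinates, which would make
#' the exponential correlation matrix singular. Before any correlation
#' matrix is formed, duplicates are separated by a deterministic offset of
#' `eps` metres: the j-th duplicate of a point is moved `eps` metres along
#' compass direction 2*pi*(j-2)/8 (a second ring at 2*eps is used beyond
#' nine coincident points). The same input always yields the same output.
#'
#' @param coords Two-column matrix of easting/northing in metres.
#' @param eps Jitter radius in metres (default 1).
#' @return Coordinates with all rows distinct.
#' @export
jitter_duplicates <- function(coords, eps = 1) {
  coords <- as.matrix(coords)
  key <- paste(format(coords[, 1], digits = 15), format(coords[, 2], digits = 15))
  groups <- split(seq_len(nrow(coords)), key)
  for (idx in groups) {
    if (length(idx) > 1L) {
      for (j in 2L:length(idx)) {
        ring <- (j - 2L) %/% 8L + 1L
        ang <- 2 * pi * ((j - 2L) %% 8L) / 8
        coords[idx[j], ] <- coords[idx[j], ] + eps * ring * c(cos(ang), sin(ang))
      }
    }
  }
  coords
}

#' Isotropic exponential correlation
#'
#' Evaluates `exp(-rho * D)` elementwise: the correlation between the
#' spatial random effects at two sites separated by distance d (km) under
#' decay parameter `rho` (per km). The effective range, the distance at
#' which correlation drops to about 0.05, is approximately `3 / rho`.
#'
#' @param D Distance matrix (km), or any nonnegative numeric array.
#' @param rho Positive spatial decay parameter (per km).
#' @return Matrix of the same shape with unit entries where `D == 0`.
#' @export
exp_correlation <- function(D, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("rho must be a single positive number")
  exp(-rho * D)
}

#' Default candidate grid for the spatial decay parameter
#'
#' Fifty geometrically spaced decay values chosen so the effective range
#' `3 / rho` spans 2% to 200% of the maximum inter-site distance. This is
#' the support of the discrete uniform prior on `rho`.
#'
#' @param D Distance matrix in km (only its maximum is used).
#' @param r Number of candidates (default 50).
#' @return Strictly increasing numeric vector of length `r`.
#' @export
default_rho_grid <- function(D, r = 50L) {
  dmax <- max(D)
  if (!is.finite(dmax) || dmax <= 0) stop("distance matrix has no positive entries")
  exp(seq(log(3 / (2 * dmax)), log(3 / (0.02 * dmax)), length.out = r))
}

#' Precompute correlation matrices for every decay candidate
#'
#' The discrete uniform prior on the decay parameter means the m x m
#' correlation matrix only ever needs to be factorised once per candidate,
#' not once per MCMC iteration. For each `rho_k` this computes a Cholesky
#' factorisation of `exp(-rho_k D)` and derives the inverse and
#' log-determinant from it; the number of factorisations performed is
#' recorded in `n_factorizations` (always exactly `length(rho_grid)`).
#'
#' @param D Symmetric distance matrix in km with zero diagonal and, after
#'   jittering, strictly positive off-diagonal entries.
#' @param rho_grid Strictly increasing vector of decay candidates.
#' @return An object of class `correlation_cache` with elements `D`,
#'   `rho_grid`, `Sinv` (list of inverses), `logdet` (vector),
#'   `Sinv_stack` (row-bound inverses for fast quadratic forms), `m`, `r`
#'   and `n_factorizations`.
#' @export
build_correlation_cache <- function(D, rho_grid) {
  D <- as.matrix(D)
  m <- nrow(D)
  if (m != ncol(D)) stop("D must be square")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  if (any(D[upper.tri(D)] <= 0))
    stop("off-diagonal distances must be strictly positive; jitter duplicated coordinates first")
  r <- length(rho_grid)
  if (r < 1L) stop("rho_grid must be nonempty")
  if (any(rho_grid <= 0)) stop("rho_grid values must be positive")
  if (r > 1L && any(diff(rho_grid) <= 0)) stop("rho_grid must be strictly increasing")

  n_fact <- 0L
  Sinv <- vector("list", r)
  logdet <- numeric(r)
  for (k in seq_len(r)) {
    S <- exp(-rho_grid[k] * D)
    U <- tryCatch(chol(S), error = function(e)
      stop("correlation matrix for rho = ", signif(rho_grid[k], 6),
           " is not positive definite: ", conditionMessage(e)))
    n_fact <- n_fact + 1L
    logdet[k] <- 2 * sum(log(diag(U)))
    Sinv[[k]] <- chol2inv(U)
  }
  structure(list(
    D = D, rho_grid = rho_grid, Sinv = Sinv, logdet = logdet,
    Sinv_stack = do.call(rbind, Sinv), m = m, r = r,
    n_factorizations = n_fact
  ), class = "correlation_cache")
}

#' @export
print.correlation_cache <- function(x, ...) {
  cat("Correlation cache:", x$m, "sites,", x$r, "decay candidates in [",
      signif(x$rho_grid[1], 4), ",", signif(x$rho_grid[x$r], 4), "] per km;",
      x$n_factorizations, "factorizations\n")
  invisible(x)
}

# Quadratic forms phi' Sinv_k phi for every candidate k in one matrix product.
quad_forms_all <- function(cache, phi) {
  tmp <- cache$Sinv_stack %*% phi
  colSums(matrix(tmp, cache$m, cache$r) * as.vector(phi))
}
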