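#' True parameters for the synthetic generative model
#'
#' The generator draws log concentrations exactly from the fusion model:
#' spatial effects `phi ~ MVN(0, sigma2 * exp(-rho D))` and observations
#' `Y = Z alpha + phi + eps`, `eps ~ N(0, nu2 sigma2 I)`. `alpha` is a
#' named vector whose names must match design-matrix columns.
#'
#' @param alpha Named coefficient vector on the log-concentration scale.
#' @param sigma2 Spatial variance (> 0).
#' @param nu2 Noise-to-signal ratio in (0, 1); the nugget is `nu2*sigma2`.
#' @param rho Spatial decay per km (> 0).
#' @return An object of class `true_params`.
#' @export
true_params <- function(alpha, sigma2, nu2, rho) {
  if (is.null(names(alpha)) || any(!nzchar(names(alpha))))
    stop("alpha must be a fully named vector")
  if (!(sigma2 > 0)) stop("sigma2 must be positive")
  if (!(nu2 > 0 && nu2 < 1)) stop("nu2 must lie in (0, 1)")
  if (!(rho > 0)) stop("rho must be positive")
  structure(list(alpha = alpha, sigma2 = sigma2, nu2 = nu2, rho = rho),
            class = "true_params")
}

#' Default true parameters
#'
#' Coefficients, variance components and decay set to the posterior
#' medians of a full-scale fit of this model to a 246-site urban NO2
#' network (intercept 1.900, log modelled 0.594, monitor 0.125,
#' environment contrasts relative to kerbside, sigma2 0.057, nu2 0.232,
#' rho 12.852 per km), so synthetic data resemble a fitted real-world
#' network.
#'
#' @return A [true_params()] object.
#' @export
default_true_params <- function() {
  true_params(
    alpha = c(`(Intercept)` = 1.900, log_modelled = 0.594,
              source_monitor = 0.125, env_roadside = -0.150,
              env_rural = -1.021, env_special = -0.390,
              env_urban_background = -0.531),
    sigma2 = 0.057, nu2 = 0.232, rho = 12.852
  )
}

#' Configuration of a synthetic study region
#'
#' Defines the rectangular extent, the regular modelled-concentration
#' grid, the monitoring-network composition (tubes, monitors, co-located
#' pairs, environment-class mix) and the generative parameters. Defaults
#' emulate the reference urban network: 230 tubes and 16 monitors
#' (8 co-located with tubes) with environment proportions
#' 142/34/8/60/2 (roadside/kerbside/special/urban background/rural)
#' out of 246.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param grid_resolution Grid cell size in metres (default 1000).
#' @param n_tubes,n_monitors Site counts by source type.
#' @param n_colocated Number of monitors placed at the exact coordinates
#'   of a tube (must not exceed `min(n_tubes, n_monitors)`).
#' @param environment_proportions Named fractions over the five
#'   environment classes; must sum to 1.
#' @param true_params A [true_params()] object.
#' @param seed Integer RNG seed.
#' @param base_pcm Rural background modelled concentration (ug/m3).
#' @param urban_amplitude Log-scale amplitude of the urban enhancement of
#'   the modelled surface at the synthetic city centre.
#' @param urban_bump_km Gaussian radius (km) of that enhancement.
#' @param urban_radius_m Cells within this distance of the centre are
#'   flagged urban.
#' @param grf_sd,grf_range_km Standard deviation and effective range (km)
#'   of the smooth log-scale random field added to the modelled surface.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(extent = c(0, 7000, 0, 7000),
                             grid_resolution = 1000,
                             n_tubes = 230L, n_monitors = 16L,
                             n_colocated = 8L,
                             environment_proportions = c(
                               kerbside = 34, roadside = 142, rural = 2,
                               special = 8, urban_background = 60) / 246,
                             true_params = default_true_params(),
                             seed = 1L,
                             base_pcm = 4.8, urban_amplitude = 1.1,
                             urban_bump_km = 2, urban_radius_m = 2200,
                             grf_sd = 0.25, grf_range_km = 2) {
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent: need c(xmin, xmax, ymin, ymax) with positive spans")
  if (grid_resolution <= 0) stop("grid_resolution must be positive")
  if ((extent[2] - extent[1]) < grid_resolution ||
      (extent[4] - extent[3]) < grid_resolution)
    stop("extent smaller than one grid cell")
  p <- environment_proportions
  if (is.null(names(p)) || !setequal(names(p), env_levels_all()))
    stop("environment_proportions must be named over: ",
         paste(env_levels_all(), collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9) stop("environment_proportions must sum to 1")
  if (any(p < 0)) stop("environment_proportions must be nonnegative")
  n_tubes <- as.integer(n_tubes); n_monitors <- as.integer(n_monitors)
  n_colocated <- as.integer(n_colocated)
  if (n_tubes < 0 || n_monitors < 0) stop("site counts must be nonnegative")
  if (n_colocated > min(n_tubes, n_monitors))
    stop("n_colocated cannot exceed min(n_tubes, n_monitors)")
  stopifnot(inherits(true_params, "true_params"))
  structure(list(
    extent = extent, grid_resolution = grid_resolution,
    n_tubes = n_tubes, n_monitors = n_monitors, n_colocated = n_colocated,
    environment_proportions = p[env_levels_all()],
    true_params = true_params, seed = as.integer(seed),
    base_pcm = base_pcm, urban_amplitude = urban_amplitude,
    urban_bump_km = urban_bump_km, urban_radius_m = urban_radius_m,
    grf_sd = grf_sd, grf_range_km = grf_range_km
  ), class = "synthetic_config")
}

#' Generate the regular modelled-concentration grid
#'
#' Lays a regular grid of cell centres over the extent and generates a
#' strictly positive modelled NO2 background surface as the exponential of
#' a smooth Gaussian random field plus a Gaussian "urban bump" centred on
#' a synthetic city centre (the extent midpoint), so urban cells carry
#' systematically higher modelled values. Cells within `urban_radius_m` of
#' the centre are flagged urban.
#'
#' @param config A [synthetic_config()].
#' @return A grid table: `cell_id`, `easting_m`, `northing_m`,
#'   `pcm_no2_ugm3`, `urban` (logical).
#' @export
generate_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  res <- config$grid_resolution
  ex <- config$extent
  nx <- floor((ex[2] - ex[1]) / res)
  ny <- floor((ex[4] - ex[3]) / res)
  centres <- expand.grid(
    easting_m = ex[1] + res * (seq_len(nx) - 0.5),
    northing_m = ex[3] + res * (seq_len(ny) - 0.5)
  )
  n <- nrow(centres)

  set.seed(config$seed)
  # Smooth log-scale field on the cell centres.
  D <- distance_matrix(centres)
  S <- exp_correlation(D, 3 / config$grf_range_km)
  L <- chol(S + diag(1e-10, n))
  field <- config$grf_sd * drop(crossprod(L, stats::rnorm(n)))

  centre_xy <- c(mean(ex[1:2]), mean(ex[3:4]))
  d_centre_km <- sqrt((centres$easting_m - centre_xy[1])^2 +
                      (centres$northing_m - centre_xy[2])^2) / 1000
  bump <- config$urban_amplitude * exp(-(d_centre_km / config$urban_bump_km)^2 / 2)

  data.frame(
    cell_id = paste0("cell_", seq_len(n)),
    easting_m = centres$easting_m,
    northing_m = centres$northing_m,
    pcm_no2_ugm3 = config$base_pcm * exp(bump + field),
    urban = d_centre_km * 1000 < config$urban_radius_m,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic monitoring network
#'
#' Samples tube and monitor locations over the grid with probability
#' proportional to each cell's modelled concentration (emulating
#' preferential siting near pollution), uniform within the chosen cell.
#' `n_colocated` monitors are placed at the exact coordinates (and
#' environment) of a tube. Tube environments are a multinomial draw from
#' `environment_proportions`; non-co-located monitors cycle through the
#' five classes first, emulating deliberate network design. Every site
#' carries the modelled value of its containing cell. Concentrations are
#' left `NA` until [simulate_observations()] fills them.
#'
#' @param config A [synthetic_config()].
#' @param grid A grid table from [generate_grid()] with the same extent.
#' @return A site table: `id`, `easting_m`, `northing_m`, `source`,
#'   `environment`, `pcm_no2_ugm3`, `no2_ugm3` (NA).
#' @export
generate_sites <- function(config, grid) {
  stopifnot(inherits(config, "synthetic_config"))
  n_sites <- config$n_tubes + config$n_monitors
  if (n_sites > 50 * nrow(grid))
    stop("requested site count exceeds what the extent can plausibly hold")
  if (config$n_tubes + config$n_monitors == 0) stop("no sites requested")
  res <- config$grid_resolution
  set.seed(config$seed + 1L)

  sample_points <- function(n) {
    cells <- sample.int(nrow(grid), n, replace = TRUE,
                        prob = grid$pcm_no2_ugm3)
    data.frame(
      easting_m = grid$easting_m[cells] + stats::runif(n, -res / 2, res / 2),
      northing_m = grid$northing_m[cells] + stats::runif(n, -res / 2, res / 2),
      pcm_no2_ugm3 = grid$pcm_no2_ugm3[cells]
    )
  }

  props <- config$environment_proportions
  tubes <- sample_points(config$n_tubes)
  tubes$source <- "tube"
  tubes$environment <- sample(names(props), config$n_tubes,
                              replace = TRUE, prob = props)

  n_mon <- config$n_monitors
  monitors <- NULL
  if (n_mon > 0) {
    n_col <- config$n_colocated
    n_free <- n_mon - n_col
    free <- if (n_free > 0) sample_points(n_free) else NULL
    if (!is.null(free)) {
      free$source <- "monitor"
      cyc <- rep_len(sample(env_levels_all()), min(n_free, 5L))
      extra <- if (n_free > 5L)
        sample(names(props), n_free - 5L, replace = TRUE, prob = props)
      free$environment <- c(cyc, extra)[seq_len(n_free)]
    }
    coloc <- NULL
    if (n_col > 0) {
      partner <- sample.int(config$n_tubes, n_col)
      coloc <- tubes[partner, c("easting_m", "northing_m", "pcm_no2_ugm3",
                                "source", "environment")]
      coloc$source <- "monitor"
      rownames(coloc) <- NULL
    }
    monitors <- rbind(coloc, free)
  }

  sites <- rbind(tubes[, c("easting_m", "northing_m", "pcm_no2_ugm3",
                           "source", "environment")], monitors)
  rownames(sites) <- NULL
  data.frame(
    id = paste0("site_", seq_len(nrow(sites))),
    easting_m = sites$easting_m, northing_m = sites$northing_m,
    source = sites$source, environment = sites$environment,
    pcm_no2_ugm3 = sites$pcm_no2_ugm3,
    no2_ugm3 = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate observations from the fusion model's generative process
#'
#' Draws log concentrations exactly from the model: a spatial effect
#' `phi ~ MVN(0, sigma2 * exp(-rho D))` on the (deterministically
#' jittered) site coordinates, plus the covariate mean `Z alpha`, plus
#' iid nugget noise with variance `nu2 * sigma2`. Concentrations are
#' returned as `exp(Y)` in ug/m3. The realised spatial effects and the
#' mean are attached as attributes `phi_true` and `log_mean_true` so
#' downstream checks can compare against the generating truth.
#'
#' @param sites A site table (see [generate_sites()]).
#' @param spec A [covariate_spec()]; `params$alpha` must name every
#'   resulting design column.
#' @param params A [true_params()] object.
#' @param seed Integer RNG seed.
#' @return The site table with `no2_ugm3` filled in.
#' @export
simulate_observations <- function(sites, spec, params, seed = 1L) {
  stopifnot(inherits(params, "true_params"))
  Z <- build_design_matrix(sites, spec)
  missing_coef <- setdiff(colnames(Z), names(params$alpha))
  if (length(missing_coef))
    stop("params$alpha has no coefficient for column(s): ",
         paste(missing_coef, collapse = ", "))
  alpha <- params$alpha[colnames(Z)]

  coords <- jitter_duplicates(as.matrix(sites[, c("easting_m", "northing_m")]))
  D <- distance_matrix(coords)
  S <- exp_correlation(D, params$rho)
  U <- tryCatch(chol(S), error = function(e)
    stop("singular correlation matrix even after jittering: ",
         conditionMessage(e)))

  set.seed(seed)
  m <- nrow(sites)
  phi <- sqrt(params$sigma2) * drop(crossprod(U, stats::rnorm(m)))
  mu <- drop(Z %*% alpha)
  Y <- mu + phi + stats::rnorm(m, sd = sqrt(params$nu2 * params$sigma2))

  sites$no2_ugm3 <- exp(Y)
  attr(sites, "phi_true") <- phi
  attr(sites, "log_mean_true") <- mu
  sites
}
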