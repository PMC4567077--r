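# Shared fixture builders: every dataset is generated in code at test time.

# Full synthetic pipeline: grid + sites + simulated observations.
make_obs_sites <- function(n_tubes = 50, n_monitors = 10, n_colocated = 4,
                           seed = 1, spec = covariate_spec(source = TRUE,
                                                           environment = TRUE),
                           params = default_true_params(), ...) {
  cfg <- synthetic_config(n_tubes = n_tubes, n_monitors = n_monitors,
                          n_colocated = n_colocated, seed = seed,
                          true_params = params, ...)
  grid <- generate_grid(cfg)
  sites <- generate_sites(cfg, grid)
  simulate_observations(sites, spec, params, seed = seed + 500000L)
}

# Minimal hand-built site table for design-matrix tests.
toy_sites <- function() {
  data.frame(
    id = paste0("s", 1:6),
    easting_m = c(0, 1000, 2000, 3000, 4000, 5000),
    northing_m = c(0, 500, 0, 1500, 0, 2500),
    source = c("tube", "tube", "monitor", "tube", "monitor", "tube"),
    environment = c("kerbside", "roadside", "rural", "special",
                    "urban_background", "roadside"),
    pcm_no2_ugm3 = c(7.632, 5, 4, 9, 12, 6),
    no2_ugm3 = c(30, 25, 8, 20, 22, 28),
    stringsAsFactors = FALSE
  )
}

# Simple scattered coordinates (metres) for covariance tests.
toy_coords <- function(m, seed = 42, extent = 5000) {
  set.seed(seed)
  cbind(runif(m, 0, extent), runif(m, 0, extent))
}
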