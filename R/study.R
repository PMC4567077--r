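#' Nominal-coverage simulation study
#'
#' Generates replicate synthetic networks, simulates observations exactly
#' from the fusion model's own generative process at the default
#' (reference-fit) parameter values, and runs scaled-down leave-one-out
#' cross-validation
#' with the Bayesian fit on each replicate. Because the fitted model is
#' exactly the generating model, the central 95% posterior prediction
#' intervals should contain the held-out log observations close to 95%
#' of the time; the pooled coverage over all folds and replicates is the
#' study's headline check that the model's uncertainty is calibrated.
#'
#' @param n_reps Number of replicate datasets (default 5).
#' @param n_tubes,n_monitors,n_colocated Network composition per
#'   replicate (default 50/10/4, a scaled-down network).
#' @param n_burn,n_keep MCMC iterations per fold (default 500 + 1000,
#'   i.e. 1,500 total).
#' @param params Generating [true_params()] (default
#'   [default_true_params()]).
#' @param spec Generating and fitting [covariate_spec()] (default the
#'   full covariate set).
#' @param seed Base seed; replicate j derives its seeds from it.
#' @return A list with `per_replicate` (data frame of coverage, bias,
#'   rmspe per replicate), `pooled_coverage_pct` (over all folds),
#'   `mean_coverage_pct` (mean of replicate coverages) and `n_folds`.
#' @export
nominal_coverage_study <- function(n_reps = 5, n_tubes = 50, n_monitors = 10,
                                   n_colocated = 4, n_burn = 500L,
                                   n_keep = 1000L,
                                   params = default_true_params(),
                                   spec = covariate_spec(source = TRUE,
                                                         environment = TRUE),
                                   seed = 1L) {
  per <- vector("list", n_reps)
  covered <- 0L
  total <- 0L
  for (j in seq_len(n_reps)) {
    rep_seed <- seed + 7919L * j
    cfg <- synthetic_config(n_tubes = n_tubes, n_monitors = n_monitors,
                            n_colocated = n_colocated, seed = rep_seed,
                            true_params = params)
    grid <- generate_grid(cfg)
    sites <- generate_sites(cfg, grid)
    sites <- simulate_observations(sites, spec, params,
                                   seed = rep_seed + 1L)
    v <- suppressWarnings(
      loocv(sites, spec, fit_method = "mcmc", n_burn = n_burn,
            n_keep = n_keep, seed = rep_seed + 2L, max_skip_frac = 0.1))
    ok <- !is.na(v$predictions$median_log)
    covered <- covered + sum(v$predictions$lo_log[ok] <=
                               v$predictions$observed_log[ok] &
                             v$predictions$observed_log[ok] <=
                               v$predictions$hi_log[ok])
    total <- total + sum(ok)
    per[[j]] <- data.frame(replicate = j, coverage_pct = v$coverage_pct,
                           bias = v$bias, rmspe = v$rmspe,
                           n_folds = v$n_folds)
  }
  per <- do.call(rbind, per)
  list(per_replicate = per,
       pooled_coverage_pct = 100 * covered / total,
       mean_coverage_pct = mean(per$coverage_pct),
       n_folds = total)
}
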