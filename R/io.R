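# Label normalisation shared by the readers: case-fold and map
# spaces/hyphens to underscores, so "Urban Background" == "urban_background".
normalize_label <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(as.character(x))))
}

require_columns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
}

#' Read a site table from CSV
#'
#' Expected columns: `id`, `easting_m`, `northing_m`, `source`
#' (`tube`/`monitor`), `environment` (kerbside/roadside/rural/special/
#' urban_background), `pcm_no2_ugm3` (modelled background of the
#' containing grid cell) and `no2_ugm3` (observed annual mean; may be NA
#' for sites awaiting simulation). Labels are case-folded; unknown labels
#' and non-positive concentrations raise an error naming the row.
#'
#' @param path CSV path.
#' @param quiet Suppress the row-count/tally message.
#' @return A validated site table (data frame).
#' @export
read_sites <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("id", "easting_m", "northing_m", "source",
                        "environment", "pcm_no2_ugm3", "no2_ugm3"),
                  "site", path)
  df$source <- normalize_label(df$source)
  df$environment <- normalize_label(df$environment)

  bad <- which(!df$source %in% source_levels_all())
  if (length(bad))
    stop("unknown source label '", df$source[bad[1]], "' at row ", bad[1],
         " of ", path)
  bad <- which(!df$environment %in% env_levels_all())
  if (length(bad))
    stop("unknown environment label '", df$environment[bad[1]], "' at row ",
         bad[1], " of ", path)
  bad <- which(!is.na(df$no2_ugm3) & df$no2_ugm3 <= 0)
  if (length(bad))
    stop("non-positive concentration at row ", bad[1], " of ", path)
  bad <- which(!is.finite(df$pcm_no2_ugm3) | df$pcm_no2_ugm3 <= 0)
  if (length(bad))
    stop("non-positive or missing modelled concentration at row ", bad[1],
         " of ", path)
  if (anyDuplicated(df$id))
    stop("duplicated site id in ", path)
  if (!quiet)
    message(nrow(df), " sites read (",
            sum(df$source == "monitor"), " monitors, ",
            sum(df$source == "tube"), " tubes); environments: ",
            paste(names(table(df$environment)), table(df$environment),
                  sep = "=", collapse = ", "))
  df
}

#' Write a site table to CSV
#' @param sites Site table.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(sites[, c("id", "easting_m", "northing_m", "source",
                             "environment", "pcm_no2_ugm3", "no2_ugm3")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a prediction-grid table from CSV
#'
#' Expected columns: `cell_id`, `easting_m`, `northing_m`,
#' `pcm_no2_ugm3`, `urban` (logical or 0/1). Duplicated cell ids are an
#' error; cell centres not lying on a regular lattice only raise a
#' warning.
#'
#' @param path CSV path.
#' @return A validated grid table.
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("cell_id", "easting_m", "northing_m",
                        "pcm_no2_ugm3", "urban"), "grid", path)
  if (anyDuplicated(df$cell_id))
    stop("duplicated cell_id in ", path)
  if (any(is.na(df$urban))) stop("missing urban flag in ", path)
  df$urban <- as.logical(df$urban)
  if (any(is.na(df$urban))) stop("urban flag must be logical or 0/1 in ", path)
  if (any(!is.finite(df$pcm_no2_ugm3) | df$pcm_no2_ugm3 <= 0))
    stop("non-positive or missing modelled concentration in ", path)

  lattice_ok <- function(v) {
    u <- sort(unique(round(v, 6)))
    length(u) < 2L || all(abs(diff(u) - diff(u)[1]) < 1e-6 * max(abs(u), 1))
  }
  if (!lattice_ok(df$easting_m) || !lattice_ok(df$northing_m))
    warning("grid cell centres do not lie on a regular lattice")
  df
}

#' Write a grid table to CSV
#' @param grid Grid table.
#' @param path Output path.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(grid[, c("cell_id", "easting_m", "northing_m",
                            "pcm_no2_ugm3", "urban")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration names either real data (`sites`/`grid` CSV paths)
#' or a `synthetic` block (arguments to [synthetic_config()]), exactly
#' one of the two; a `covariates` block (term names: `log_modelled`,
#' `monitor_tube`, `environment`, `log_modelled:easting`,
#' `log_modelled:northing`); optional `priors` and `mcmc`
#' (`n_burn`, `n_keep`) blocks; a mandatory integer `seed`; and an
#' `output_dir`.
#'
#' @param path YAML path.
#' @return The configuration list (validated by [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# Translate a covariates term list into a covariate_spec.
spec_from_terms <- function(terms) {
  if (is.null(terms)) terms <- c("log_modelled", "environment")
  known <- c("log_modelled", "monitor_tube", "environment",
             "log_modelled:easting", "log_modelled:northing")
  unknown <- setdiff(terms, known)
  if (length(unknown))
    stop("unknown covariate term(s): ", paste(unknown, collapse = ", "))
  covariate_spec(
    log_modelled = "log_modelled" %in% terms,
    source = "monitor_tube" %in% terms,
    environment = "environment" %in% terms,
    spatial_interaction = any(c("log_modelled:easting",
                                "log_modelled:northing") %in% terms)
  )
}

#' Run the full simulate/fit/predict/validate pipeline
#'
#' Executes the pipeline described by a run configuration (a list or a
#' YAML path, see [read_run_config()]): load or simulate the data, fit
#' the fusion model, predict the grid surface, optionally run LOOCV, and
#' write all artifacts (site/grid CSVs, posterior parameter draws,
#' prediction CSV, validation CSV, a JSON manifest with the seed and
#' settings, and a log file) into the output directory. Reruns with the
#' same configuration and seed reproduce the artifacts byte for byte.
#'
#' @param config A configuration list or YAML path.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("config must name an output_dir")
  if (is.null(config$seed)) stop("config must name a seed")
  seed <- as.integer(config$seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  unlink(log_path)

  has_paths <- !is.null(config$sites) || !is.null(config$grid)
  has_synth <- !is.null(config$synthetic)
  if (has_paths == has_synth)
    stop("config must name exactly one of (sites/grid paths, synthetic block)")

  spec <- spec_from_terms(config$covariates)

  if (has_synth) {
    logf("generating synthetic data")
    syn <- config$synthetic
    syn$seed <- seed
    cfg <- do.call(synthetic_config, syn)
    grid <- generate_grid(cfg)
    sites <- generate_sites(cfg, grid)
    sites <- simulate_observations(sites, spec, cfg$true_params, seed = seed)
    write_sites(sites, file.path(out, "sites.csv"))
    write_grid(grid, file.path(out, "grid.csv"))
  } else {
    logf("reading data")
    sites <- read_sites(config$sites, quiet = TRUE)
    grid <- read_grid(config$grid)
    if (any(is.na(sites$no2_ugm3)))
      stop("site file has missing concentrations; cannot fit")
  }

  mc <- config$mcmc %||% list()
  n_burn <- as.integer(mc$n_burn %||% 2000L)
  n_keep <- as.integer(mc$n_keep %||% 1000L)
  pr <- config$priors %||% list()
  priors <- prior_spec(alpha_prior_var = pr$alpha_prior_var %||% 1000,
                       ig_a = pr$ig_a %||% 0.001, ig_b = pr$ig_b %||% 0.001)

  logf("fitting (", n_burn, " burn-in + ", n_keep, " retained)")
  fit <- fit_fusion(sites, spec, method = "mcmc", priors = priors,
                    n_burn = n_burn, n_keep = n_keep, seed = seed)
  s <- fit$fit
  utils::write.csv(
    data.frame(s$alpha, sigma2 = s$sigma2, nu2 = s$nu2, rho = s$rho,
               check.names = FALSE),
    file.path(out, "posterior_draws.csv"), row.names = FALSE)

  logf("predicting ", nrow(grid), " grid cells")
  pg <- predict_grid(fit, grid, seed = seed)
  attr(pg, "draws") <- NULL
  utils::write.csv(format_num(pg), file.path(out, "predictions.csv"),
                   row.names = FALSE)

  val <- NULL
  if (isTRUE(config$validate)) {
    vset <- config$validation %||% list()
    logf("leave-one-out validation")
    val <- loocv(sites, spec, fit_method = "mcmc",
                 n_burn = as.integer(vset$n_burn %||% 500L),
                 n_keep = as.integer(vset$n_keep %||% 1000L),
                 seed = seed, priors = priors, label = "pipeline")
    utils::write.csv(as.data.frame(val), file.path(out, "validation.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = seed, covariates = config$covariates,
    mcmc = list(n_burn = n_burn, n_keep = n_keep),
    synthetic = has_synth, n_sites = nrow(sites), n_cells = nrow(grid),
    nu2_acceptance = s$acc_rate,
    package_version = as.character(utils::packageVersion("geofuse"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done")
  invisible(out)
}

# Stable numeric formatting so identical runs give identical CSV bytes.
format_num <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
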