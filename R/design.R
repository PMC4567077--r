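# Closed vocabularies for the site metadata columns.
env_levels_all <- function() c("kerbside", "roadside", "rural", "special", "urban_background")
source_levels_all <- function() c("tube", "monitor")

#' Declare the covariate set of a fusion model
#'
#' The fusion model's mean is a linear combination of an intercept and any
#' of: the natural log of the modelled (dispersion-model) concentration,
#' a monitor/tube indicator, the local-environment class, and an
#' interaction between log modelled and the (centred, scaled) easting and
#' northing coordinates which lets the calibration of the modelled surface
#' vary smoothly over space.
#'
#' @param log_modelled Include `log(pcm_no2_ugm3)`? (default TRUE)
#' @param source Include the monitor-vs-tube indicator? (reference: tube)
#' @param environment Include the local-environment factor?
#'   (reference: kerbside)
#' @param spatial_interaction Include `log_modelled:easting` and
#'   `log_modelled:northing`? Requires `log_modelled = TRUE`.
#' @param ref_source,ref_environment Reference levels for the dummy coding.
#' @return An object of class `covariate_spec`.
#' @seealso [standard_model_specs()] for the nine specifications compared
#'   in the validation study.
#' @export
covariate_spec <- function(log_modelled = TRUE, source = FALSE,
                           environment = FALSE, spatial_interaction = FALSE,
                           ref_source = "tube", ref_environment = "kerbside") {
  if (spatial_interaction && !log_modelled)
    stop("spatial_interaction requires log_modelled")
  if (!ref_source %in% source_levels_all())
    stop("ref_source must be one of: ", paste(source_levels_all(), collapse = ", "))
  if (!ref_environment %in% env_levels_all())
    stop("ref_environment must be one of: ", paste(env_levels_all(), collapse = ", "))
  structure(list(
    log_modelled = isTRUE(log_modelled), source = isTRUE(source),
    environment = isTRUE(environment),
    spatial_interaction = isTRUE(spatial_interaction),
    ref_source = ref_source, ref_environment = ref_environment
  ), class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  terms <- c("1",
             if (x$log_modelled) "log_modelled",
             if (x$source) "monitor/tube",
             if (x$environment) "environment",
             if (x$spatial_interaction) c("log_modelled:easting", "log_modelled:northing"))
  cat("Covariate spec: ", paste(terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Build the covariate (design) matrix for a site table
#'
#' Expands a [covariate_spec()] against a site table into the m x p design
#' matrix used by all fitting routines. The first column is the intercept.
#' The modelled concentration enters as its natural log; factors are
#' dummy-coded against the spec's reference levels; interaction columns
#' multiply `log_modelled` by coordinates centred at the site centroid and
#' scaled to units of 10 km (raw metre coordinates would make the matrix
#' severely ill-conditioned). The centring constants and observed factor
#' levels are stored as attributes so exactly the same transform can be
#' applied at prediction locations.
#'
#' @param sites A site table (see [read_sites()] for the schema).
#' @param spec A [covariate_spec()].
#' @param template Optional design matrix previously returned by this
#'   function; when supplied, its centring constants and factor levels are
#'   reused and an error is raised for factor levels unseen in the
#'   template (the prediction-time contract).
#' @return A numeric matrix with attributes `spec`, `centering`,
#'   `env_levels` (levels present, reference first) and `source_levels`.
#' @export
build_design_matrix <- function(sites, spec, template = NULL) {
  stopifnot(inherits(spec, "covariate_spec"))
  m <- nrow(sites)
  cols <- list(`(Intercept)` = rep(1, m))

  tmpl_attr <- function(what) if (is.null(template)) NULL else attr(template, what)

  if (spec$log_modelled || spec$spatial_interaction) {
    pcm <- sites$pcm_no2_ugm3
    if (is.null(pcm)) stop("sites must carry a pcm_no2_ugm3 column for log_modelled")
    bad <- which(!is.finite(pcm) | pcm <= 0)
    if (length(bad))
      stop("non-positive or missing modelled concentration at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    log_mod <- log(pcm)
    cols$log_modelled <- log_mod
  }

  src_levels <- tmpl_attr("source_levels")
  if (spec$source) {
    src <- as.character(sites$source)
    unknown <- setdiff(unique(src), source_levels_all())
    if (length(unknown)) stop("unknown source label(s): ", paste(unknown, collapse = ", "))
    if (is.null(src_levels)) {
      present <- intersect(source_levels_all(), unique(src))
      ref <- if (spec$ref_source %in% present) spec$ref_source else present[1]
      src_levels <- c(ref, setdiff(present, ref))
    } else {
      unseen <- setdiff(unique(src), src_levels)
      if (length(unseen))
        stop("unseen source level at prediction time: ", paste(unseen, collapse = ", "))
    }
    for (lev in src_levels[-1])
      cols[[paste0("source_", lev)]] <- as.numeric(src == lev)
  }

  env_levels <- tmpl_attr("env_levels")
  if (spec$environment) {
    env <- as.character(sites$environment)
    unknown <- setdiff(unique(env), env_levels_all())
    if (length(unknown)) stop("unknown environment label(s): ", paste(unknown, collapse = ", "))
    if (is.null(env_levels)) {
      present <- intersect(env_levels_all(), unique(env))
      ref <- if (spec$ref_environment %in% present) spec$ref_environment else present[1]
      env_levels <- c(ref, setdiff(present, ref))
    } else {
      unseen <- setdiff(unique(env), env_levels)
      if (length(unseen))
        stop("unseen environment level at prediction time: ", paste(unseen, collapse = ", "))
    }
    for (lev in env_levels[-1])
      cols[[paste0("env_", lev)]] <- as.numeric(env == lev)
  }

  centering <- tmpl_attr("centering")
  if (spec$spatial_interaction) {
    if (is.null(centering)) {
      centering <- list(easting = mean(sites$easting_m),
                        northing = mean(sites$northing_m),
                        scale = 10000)
    }
    cx <- (sites$easting_m - centering$easting) / centering$scale
    cy <- (sites$northing_m - centering$northing) / centering$scale
    cols[["log_modelled:easting"]] <- log_mod * cx
    cols[["log_modelled:northing"]] <- log_mod * cy
  }

  Z <- do.call(cbind, cols)
  colnames(Z) <- names(cols)

  # Drop degenerate (constant) non-intercept columns, e.g. the source
  # indicator when a fit uses only one source type; remember what was kept
  # so prediction rebuilds the identical matrix.
  keep <- tmpl_attr("columns")
  if (is.null(keep)) {
    constant <- vapply(seq_len(ncol(Z)), function(j)
      j > 1L && m > 1L && stats::sd(Z[, j]) == 0, logical(1))
    keep <- colnames(Z)[!constant]
  }
  Z <- Z[, intersect(colnames(Z), keep), drop = FALSE]

  structure(Z, spec = spec, centering = centering,
            env_levels = env_levels, source_levels = src_levels,
            columns = keep)
}
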