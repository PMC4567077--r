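#' Mean prediction bias
#'
#' Mean of (prediction - observation); positive values mean
#' over-prediction. Computed on whatever scale the inputs are on (the
#' package's validation pipeline uses the log scale, the modelling
#' scale).
#'
#' @param predicted,observed Equal-length finite numeric vectors.
#' @return A scalar.
#' @export
bias <- function(predicted, observed) {
  check_pred_obs(predicted, observed)
  mean(predicted - observed)
}

#' Root mean square prediction error
#'
#' Square root of the mean squared difference between predictions and
#' observations. `rmspe(p, o)^2 >= bias(p, o)^2` always (mean-square
#' versus square-of-mean).
#'
#' @inheritParams bias
#' @return A nonnegative scalar.
#' @export
rmspe <- function(predicted, observed) {
  check_pred_obs(predicted, observed)
  sqrt(mean((predicted - observed)^2))
}

check_pred_obs <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("predicted and observed must be finite")
  invisible(TRUE)
}

#' Empirical coverage of prediction intervals
#'
#' Percentage of closed intervals `[lower, upper]` containing the
#' observation.
#'
#' @param lower,upper Interval endpoints, `lower <= upper` elementwise
#'   (infinite endpoints allowed).
#' @param observed Observations, same length.
#' @return A percentage in `[0, 100]`.
#' @export
coverage <- function(lower, upper, observed) {
  if (length(lower) != length(upper) || length(lower) != length(observed))
    stop("lower, upper and observed must have equal length")
  if (any(is.na(lower)) || any(is.na(upper)))
    stop("malformed interval: NA endpoint")
  if (any(lower > upper)) stop("malformed interval: lower > upper")
  100 * mean(lower <= observed & observed <= upper)
}

#' Leave-one-out cross-validation of a fusion model
#'
#' Removes each site in turn, refits on the remainder, predicts the
#' held-out site by the fitted method's two-step procedure (for MCMC the
#' point prediction is the posterior median of the predictive draws and
#' the interval their central 95%), and accumulates bias, RMSPE and
#' interval coverage on the log scale. A fold whose prediction fails
#' (e.g. a factor level unseen once its only site is held out) is skipped
#' with a warning; more than `max_skip_frac` skipped folds is an error.
#' When a held-out site is co-located with another, the retained twin
#' stays in the training set.
#'
#' @param sites Site table with observed concentrations (m >= 10).
#' @param spec A [covariate_spec()].
#' @param fit_method `"mcmc"`, `"reml"` or `"ols"`.
#' @param n_burn,n_keep MCMC settings per fold (scaled-down defaults for
#'   routine validation; raise for production runs).
#' @param seed Base seed; fold i uses `seed + i`.
#' @param priors A [prior_spec()].
#' @param level Interval probability.
#' @param label Free-text model label carried into the summary.
#' @param max_skip_frac Maximum tolerated fraction of skipped folds.
#' @param folds Optional subset of site indices to hold out (default all).
#' @return An object of class `fusion_loocv`: the per-site prediction
#'   table and the summary metrics (`bias`, `rmspe`, `coverage_pct`,
#'   `n_sites`, `n_skipped`).
#' @export
loocv <- function(sites, spec, fit_method = c("mcmc", "reml", "ols"),
                  n_burn = 500L, n_keep = 1000L, seed = 1L,
                  priors = prior_spec(), level = 0.95, label = NULL,
                  max_skip_frac = 0.05, folds = NULL) {
  fit_method <- match.arg(fit_method)
  m <- nrow(sites)
  if (m < 10L) stop("leave-one-out validation needs at least 10 sites")
  if (is.null(folds)) folds <- seq_len(m)
  if (is.null(label)) label <- fit_method

  pred <- data.frame(site = folds, observed_log = log(sites$no2_ugm3[folds]),
                     median_log = NA_real_, lo_log = NA_real_,
                     hi_log = NA_real_)
  skipped <- character(0)

  for (j in seq_along(folds)) {
    i <- folds[j]
    res <- tryCatch({
      fit <- fit_fusion(sites[-i, , drop = FALSE], spec, method = fit_method,
                        priors = priors, n_burn = n_burn, n_keep = n_keep,
                        seed = seed + i)
      p <- predict(fit, sites[i, , drop = FALSE], level = level,
                   seed = seed + i)
      p[1, c("median_log", "lo_log", "hi_log")]
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, paste0("site ", i, ": ", conditionMessage(res)))
      next
    }
    pred[j, c("median_log", "lo_log", "hi_log")] <- res
  }

  if (length(skipped)) {
    warning(length(skipped), " fold(s) skipped: ",
            paste(utils::head(skipped, 3), collapse = "; "))
    if (length(skipped) / length(folds) > max_skip_frac)
      stop("more than ", round(100 * max_skip_frac), "% of folds failed (",
           length(skipped), "/", length(folds), ")")
  }
  ok <- !is.na(pred$median_log)
  structure(list(
    predictions = pred, label = label, method = fit_method,
    bias = bias(pred$median_log[ok], pred$observed_log[ok]),
    rmspe = rmspe(pred$median_log[ok], pred$observed_log[ok]),
    coverage_pct = coverage(pred$lo_log[ok], pred$hi_log[ok],
                            pred$observed_log[ok]),
    n_sites = m, n_folds = sum(ok), n_skipped = length(skipped)
  ), class = "fusion_loocv")
}

#' @export
print.fusion_loocv <- function(x, ...) {
  cat("LOOCV [", x$label, "]: bias ", signif(x$bias, 3), ", RMSPE ",
      signif(x$rmspe, 4), ", coverage ", round(x$coverage_pct, 1),
      "% over ", x$n_folds, " folds",
      if (x$n_skipped) paste0(" (", x$n_skipped, " skipped)"), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fusion_loocv <- function(x, ...) {
  data.frame(label = x$label, method = x$method, bias = x$bias,
             rmspe = x$rmspe, coverage_pct = x$coverage_pct,
             n_sites = x$n_sites, n_folds = x$n_folds,
             n_skipped = x$n_skipped, stringsAsFactors = FALSE)
}

#' The nine model specifications of the covariate comparison study
#'
#' Models 1-3 share the full covariate set (log modelled + monitor/tube +
#' environment) and differ by estimation method (Bayesian MCMC, REML,
#' OLS); Models 4-9 are Bayesian with nested covariate subsets, Models 8
#' and 9 adding the log modelled by easting/northing interaction.
#'
#' @return A named list of `list(label, spec, method)` entries.
#' @export
standard_model_specs <- function() {
  full <- covariate_spec(log_modelled = TRUE, source = TRUE, environment = TRUE)
  list(
    model1 = list(label = "log modelled + monitor/tube + environment (MCMC)",
                  spec = full, method = "mcmc"),
    model2 = list(label = "as model 1, REML", spec = full, method = "reml"),
    model3 = list(label = "as model 1, OLS (non-spatial)", spec = full,
                  method = "ols"),
    model4 = list(label = "log modelled",
                  spec = covariate_spec(), method = "mcmc"),
    model5 = list(label = "log modelled + monitor/tube",
                  spec = covariate_spec(source = TRUE), method = "mcmc"),
    model6 = list(label = "log modelled + environment",
                  spec = covariate_spec(environment = TRUE), method = "mcmc"),
    model7 = list(label = "monitor/tube + environment",
                  spec = covariate_spec(log_modelled = FALSE, source = TRUE,
                                        environment = TRUE), method = "mcmc"),
    model8 = list(label = "full + spatial interaction",
                  spec = covariate_spec(source = TRUE, environment = TRUE,
                                        spatial_interaction = TRUE),
                  method = "mcmc"),
    model9 = list(label = "log modelled + environment + spatial interaction",
                  spec = covariate_spec(environment = TRUE,
                                        spatial_interaction = TRUE),
                  method = "mcmc")
  )
}

#' Compare covariate specifications and estimation methods by LOOCV
#'
#' Runs [loocv()] for each (spec, method) pair and stacks the summaries,
#' reproducing the design of the model-comparison validation study on any
#' dataset.
#'
#' @param sites Site table.
#' @param models A list of `list(label, spec, method)` entries, e.g.
#'   [standard_model_specs()].
#' @param ... Passed to [loocv()] (chain lengths, seed, ...).
#' @return A data frame with one row per model.
#' @export
compare_models <- function(sites, models, ...) {
  rows <- lapply(models, function(mod) {
    as.data.frame(loocv(sites, mod$spec, fit_method = mod$method,
                        label = mod$label, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(models)
  out
}

#' Compare data sources: monitors only, tubes only, combined
#'
#' Fits the model to each subset of the network and predicts every site
#' in the full table: a site inside the training subset is predicted by
#' refitting without it (leave-one-out); a site outside the subset is
#' predicted directly from the subset fit. Summaries are over all sites,
#' mirroring the study design that predicts each of the m observations in
#' turn from each data source.
#'
#' @param sites Full site table (must contain both sources).
#' @param spec A [covariate_spec()].
#' @param subsets Character vector among `"monitors"`, `"tubes"`,
#'   `"both"`.
#' @param n_burn,n_keep,seed,priors,level As in [loocv()].
#' @param max_skip_frac Maximum tolerated fraction of failed predictions.
#' @return A data frame with one row per subset.
#' @export
compare_data_sources <- function(sites, spec,
                                 subsets = c("monitors", "tubes", "both"),
                                 n_burn = 500L, n_keep = 1000L, seed = 1L,
                                 priors = prior_spec(), level = 0.95,
                                 max_skip_frac = 0.05) {
  m <- nrow(sites)
  rows <- lapply(subsets, function(sub) {
    in_sub <- switch(sub,
      monitors = sites$source == "monitor",
      tubes = sites$source == "tube",
      both = rep(TRUE, m),
      stop("unknown subset: ", sub))
    idx <- which(in_sub)
    if (length(idx) < 10L)
      stop("subset '", sub, "' has fewer than 10 sites")

    pred <- data.frame(site = seq_len(m), observed_log = log(sites$no2_ugm3),
                       median_log = NA_real_, lo_log = NA_real_,
                       hi_log = NA_real_)
    skipped <- 0L

    predict_one <- function(train_idx, target_idx, fold_seed) {
      tryCatch({
        fit <- fit_fusion(sites[train_idx, , drop = FALSE], spec,
                          method = "mcmc", priors = priors, n_burn = n_burn,
                          n_keep = n_keep, seed = fold_seed)
        predict(fit, sites[target_idx, , drop = FALSE], level = level,
                seed = fold_seed)
      }, error = function(e) NULL)
    }

    # Sites outside the subset: one fit on the whole subset predicts them.
    out_idx <- setdiff(seq_len(m), idx)
    if (length(out_idx)) {
      p <- predict_one(idx, out_idx, seed)
      if (is.null(p)) skipped <- skipped + length(out_idx)
      else pred[out_idx, c("median_log", "lo_log", "hi_log")] <-
          p[, c("median_log", "lo_log", "hi_log")]
    }
    # Sites inside the subset: leave-one-out refits.
    for (i in idx) {
      p <- predict_one(setdiff(idx, i), i, seed + i)
      if (is.null(p)) skipped <- skipped + 1L
      else pred[i, c("median_log", "lo_log", "hi_log")] <-
          p[1, c("median_log", "lo_log", "hi_log")]
    }

    if (skipped / m > max_skip_frac)
      stop("subset '", sub, "': more than ", round(100 * max_skip_frac),
           "% of predictions failed")
    ok <- !is.na(pred$median_log)
    data.frame(
      source = sub, n_fit = length(idx),
      bias = bias(pred$median_log[ok], pred$observed_log[ok]),
      rmspe = rmspe(pred$median_log[ok], pred$observed_log[ok]),
      coverage_pct = coverage(pred$lo_log[ok], pred$hi_log[ok],
                              pred$observed_log[ok]),
      n_predicted = sum(ok), n_skipped = skipped,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline: modelled concentrations with a roadside adjustment
#'
#' The no-spatial-model baseline the fusion model is judged against: each
#' site's log concentration is predicted by its log modelled (grid
#' background) value plus an additive adjustment fitted by OLS on a
#' roadside-or-kerbside indicator (background grid values miss the
#' traffic increment at road-adjacent sites). Evaluated by leave-one-out
#' cross-validation on the log scale.
#'
#' @param sites Site table.
#' @param level Interval probability.
#' @return A `fusion_loocv` object labelled `"pcm_baseline"`.
#' @export
pcm_baseline <- function(sites, level = 0.95) {
  m <- nrow(sites)
  if (m < 10L) stop("need at least 10 sites")
  if (any(!is.finite(sites$pcm_no2_ugm3) | sites$pcm_no2_ugm3 <= 0))
    stop("sites must carry positive modelled concentrations")
  ratio <- log(sites$no2_ugm3) - log(sites$pcm_no2_ugm3)
  road <- as.numeric(sites$environment %in% c("roadside", "kerbside"))

  pred <- data.frame(site = seq_len(m), observed_log = log(sites$no2_ugm3),
                     median_log = NA_real_, lo_log = NA_real_,
                     hi_log = NA_real_)
  for (i in seq_len(m)) {
    dat <- data.frame(ratio = ratio[-i], road = road[-i])
    fit <- stats::lm(ratio ~ road, data = dat)
    pr <- stats::predict(fit, newdata = data.frame(road = road[i]),
                         interval = "prediction", level = level)
    pred[i, c("median_log", "lo_log", "hi_log")] <-
      log(sites$pcm_no2_ugm3[i]) + pr[1, c("fit", "lwr", "upr")]
  }
  structure(list(
    predictions = pred, label = "pcm_baseline", method = "ols",
    bias = bias(pred$median_log, pred$observed_log),
    rmspe = rmspe(pred$median_log, pred$observed_log),
    coverage_pct = coverage(pred$lo_log, pred$hi_log, pred$observed_log),
    n_sites = m, n_folds = m, n_skipped = 0L
  ), class = "fusion_loocv")
}
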