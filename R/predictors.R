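#' Configure a prediction strategy
#'
#' Two strategies are supported. `"SPM"` is the static prediction model: a
#' conventional Cox regression of the follow-up time on baseline
#' covariates, one row per subject. `"GLA"` is the generalized landmark
#' analysis: for each query, landmark rows are kernel-weighted around the
#' query's current value of the landmark variable(s) and a weighted Cox
#' model is fitted locally; localizing on `"time"` recovers the classical
#' landmark analysis.
#'
#' @param strategy `"SPM"` or `"GLA"`.
#' @param kernel_spec a [kernel_spec()] (required for GLA).
#' @param covariates names of the covariates in the linear predictor,
#'   excluding the landmark variable(s) unless `adjust_landmark_linear`.
#' @param adjust_landmark_linear also include the landmark variable(s) as
#'   linear covariates inside each neighborhood, guarding against
#'   within-neighborhood trend bias. Default: `TRUE`, except `FALSE` when
#'   the only landmark variable is `"time"` (classical landmark analysis
#'   absorbs the landmark time into the baseline hazard).
#' @param horizon default prediction horizon tau.
#' @param min_events sparse-neighborhood guard passed to
#'   [compute_weights()] (default 10).
#' @param spm_mode how the SPM predicts at follow-up visits: `"current"`
#'   (default) plugs the visit's current covariate values into the
#'   baseline-trained model; `"baseline"` carries the subject's baseline
#'   covariates forward.
#' @param control a [cox_control()].
#' @param seed integer seed recorded with the config.
#' @return A `predictor_config` object.
#' @export
predictor_config <- function(strategy = c("GLA", "SPM"), kernel_spec = NULL,
                             covariates, adjust_landmark_linear = NULL,
                             horizon = NULL, min_events = 10,
                             spm_mode = c("current", "baseline"),
                             control = cox_control(), seed = 1L) {
  strategy <- match.arg(strategy)
  spm_mode <- match.arg(spm_mode)
  if (strategy == "GLA") {
    if (!inherits(kernel_spec, "kernel_spec")) {
      stop("GLA requires a kernel_spec")
    }
    if (is.null(adjust_landmark_linear)) {
      adjust_landmark_linear <- !identical(kernel_spec$variables, "time")
    }
    lmk_cols <- landmark_covariate_names(kernel_spec$variables)
    if (!adjust_landmark_linear && any(lmk_cols %in% covariates)) {
      stop("covariates must exclude the landmark variable(s) unless ",
           "adjust_landmark_linear = TRUE")
    }
  } else {
    adjust_landmark_linear <- isTRUE(adjust_landmark_linear)
  }
  structure(list(strategy = strategy, kernel_spec = kernel_spec,
                 covariates = covariates,
                 adjust_landmark_linear = adjust_landmark_linear,
                 horizon = horizon, min_events = min_events,
                 spm_mode = spm_mode, control = control, seed = seed),
            class = "predictor_config")
}

# column names behind landmark variables ("time" lives in visit_time)
landmark_covariate_names <- function(vars) {
  ifelse(vars == "time", "visit_time", vars)
}

# the covariates actually entering a fit's linear predictor
effective_covariates <- function(config) {
  covs <- config$covariates
  if (config$strategy == "GLA" && config$adjust_landmark_linear) {
    covs <- union(covs, landmark_covariate_names(config$kernel_spec$variables))
  }
  covs
}

#' Fit the static prediction model
#'
#' One unit-weight Cox fit on the baseline rows only (one row per subject:
#' follow-up time, event, baseline covariates). Subjects whose follow-up
#' ends at time 0 cannot contribute a positive residual time and are
#' dropped.
#'
#' @param x a `gla_cohort` in which every subject has a baseline visit at
#'   time 0.
#' @param config a [predictor_config()].
#' @return A `local_cox_fit`.
#' @export
fit_spm <- function(x, config) {
  stopifnot(inherits(x, "gla_cohort"), inherits(config, "predictor_config"))
  base <- baseline_rows(x)
  fit_weighted_cox(base, weights = NULL,
                   covariates = effective_covariates(config),
                   control = config$control)
}

# baseline visits recast as a one-row-per-subject landmark dataset
baseline_rows <- function(x) {
  first <- x$visits[!duplicated(x$visits$subject_id), , drop = FALSE]
  if (any(first$visit_time != 0)) {
    stop("every subject needs a baseline visit at time 0 for the SPM")
  }
  idx <- match(first$subject_id, x$subjects$subject_id)
  lm <- data.frame(subject_id = first$subject_id,
                   visit_time = 0,
                   residual_time = x$subjects$followup_time[idx],
                   event = x$subjects$event[idx])
  for (nm in x$covariate_names) lm[[nm]] <- first[[nm]]
  lm <- lm[lm$residual_time > 0, , drop = FALSE]
  rownames(lm) <- NULL
  structure(lm, covariate_names = x$covariate_names, n_dropped = 0,
            class = c("landmark_dataset", "data.frame"))
}

#' Predict residual risk for one query with generalized landmark analysis
#'
#' Reads the query's landmark-variable value(s), computes kernel weights
#' over the training landmark dataset, fits a weighted Cox model on the
#' configured covariates (plus the landmark variables linearly, when
#' `adjust_landmark_linear`), and evaluates the horizon-specific event
#' probability at the query's covariates.
#'
#' @param training a `landmark_dataset` (the training half, stacked).
#' @param config a GLA [predictor_config()].
#' @param query named numeric vector or one-row data.frame with the
#'   query visit's covariates (including `visit_time` when the landmark
#'   variable is `"time"`).
#' @param horizon prediction horizon; defaults to `config$horizon`.
#' @return A `risk_prediction` (see [predict_risk()]); the local fit is
#'   attached as attribute `"fit"`.
#' @export
predict_gla <- function(training, config, query, horizon = NULL) {
  stopifnot(inherits(config, "predictor_config"),
            config$strategy == "GLA")
  if (is.null(horizon)) horizon <- config$horizon
  if (is.null(horizon)) stop("no horizon supplied")
  q <- if (is.data.frame(query)) {
    nums <- vapply(query, is.numeric, logical(1))
    unlist(query[1, nums, drop = FALSE])
  } else unlist(query)
  vars <- config$kernel_spec$variables
  qcols <- landmark_covariate_names(vars)
  if (!all(qcols %in% names(q))) {
    stop("query must provide value(s) for: ", paste(qcols, collapse = ", "))
  }
  wv <- compute_weights(training, config$kernel_spec,
                        stats::setNames(q[qcols], vars),
                        min_events = config$min_events)
  fit <- fit_weighted_cox(training, wv, effective_covariates(config),
                          control = config$control)
  out <- predict_risk(fit, q, horizon, allow_unconverged = TRUE)
  attr(out, "fit") <- fit
  out
}

#' Predict residual risk at many query visits
#'
#' The reference semantics refits one weighted Cox model per query
#' (`grid_size = NULL`). For large validation sets a grid-precompute
#' approximation is available for a single landmark variable: local models
#' are fitted at `grid_size` quantile points of the landmark variable and
#' each query's log cumulative hazard at the horizon is interpolated
#' linearly between the two neighboring grid fits (queries outside the
#' grid use the boundary fit). The approximation error is documented in the
#' package tests on simulated cohorts.
#'
#' @param training a `landmark_dataset`.
#' @param config a GLA [predictor_config()].
#' @param queries data.frame of query rows (covariates plus `visit_time`).
#' @param horizon prediction horizon; defaults to `config$horizon`.
#' @param grid_size integer number of grid points, or `NULL` for per-query
#'   refits.
#' @return Numeric vector of event probabilities, one per query row.
#' @export
predict_gla_many <- function(training, config, queries, horizon = NULL,
                             grid_size = NULL) {
  if (is.null(horizon)) horizon <- config$horizon
  if (is.null(grid_size)) {
    return(vapply(seq_len(nrow(queries)), function(i) {
      predict_gla(training, config, queries[i, , drop = FALSE],
                  horizon)$probability
    }, numeric(1)))
  }
  gf <- gla_grid_fits(training, config, grid_size)
  predict_from_grid(gf, queries, horizon)
}

# fit local models at quantile grid points of a single landmark variable
gla_grid_fits <- function(training, config, grid_size) {
  vars <- config$kernel_spec$variables
  if (length(vars) != 1) {
    stop("grid precompute supports a single landmark variable")
  }
  col <- landmark_column(training, vars)
  grid <- unique(stats::quantile(col, probs = (seq_len(grid_size) - 0.5) /
                                   grid_size, names = FALSE, type = 7))
  fits <- lapply(grid, function(v) {
    wv <- compute_weights(training, config$kernel_spec,
                          stats::setNames(v, vars),
                          min_events = config$min_events)
    fit_weighted_cox(training, wv, effective_covariates(config),
                     control = config$control)
  })
  list(grid = grid, fits = fits, config = config)
}

predict_from_grid <- function(gf, queries, horizon) {
  vars <- gf$config$kernel_spec$variables
  qcol <- landmark_covariate_names(vars)
  v <- queries[[qcol]]
  grid <- gf$grid
  # per-grid-point log cumulative hazard for every query
  logH <- vapply(gf$fits, function(fit) {
    H <- eval_cumhaz(fit, horizon) *
      exp(drop(sweep(as.matrix(queries[, names(fit$coefficients),
                                       drop = FALSE]), 2,
                     fit$center) %*% fit$coefficients))
    log(pmax(H, 1e-300))
  }, numeric(nrow(queries)))
  logH <- matrix(logH, nrow = nrow(queries))
  lo <- findInterval(v, grid)
  lo <- pmin(pmax(lo, 1), length(grid) - 1)
  hi <- lo + 1
  t_frac <- (v - grid[lo]) / (grid[hi] - grid[lo])
  t_frac <- pmin(pmax(t_frac, 0), 1)  # clamp outside the grid
  lh <- (1 - t_frac) * logH[cbind(seq_along(v), lo)] +
    t_frac * logH[cbind(seq_along(v), hi)]
  1 - exp(-exp(lh))
}

# -- method dispatch used by the evaluation protocol ------------------------

fit_method <- function(train, config, grid_size = NULL) {
  if (config$strategy == "SPM") {
    list(type = "spm", fit = fit_spm(train, config), config = config,
         baseline_visits = baseline_rows(train))
  } else {
    training <- build_landmark_dataset(train)
    gf <- if (!is.null(grid_size) &&
              length(config$kernel_spec$variables) == 1) {
      gla_grid_fits(training, config, grid_size)
    } else NULL
    list(type = "gla", training = training, config = config, grid = gf)
  }
}

predict_method <- function(model, queries, horizon) {
  if (model$type == "spm") {
    if (model$config$spm_mode == "baseline") {
      base <- model$baseline_visits
      idx <- match(queries$subject_id, base$subject_id)
      qb <- base[idx, , drop = FALSE]
      return(predict_risk_many(model$fit, qb, horizon))
    }
    predict_risk_many(model$fit, queries, horizon)
  } else if (!is.null(model$grid)) {
    predict_from_grid(model$grid, queries, horizon)
  } else {
    predict_gla_many(model$training, model$config, queries, horizon)
  }
}

#' Select the span by cross-validated prediction accuracy
#'
#' Runs the half-split cross-validation protocol within the training
#' cohort for every candidate span and scores each by the cross-validated
#' Brier score (the primary, more sensitive criterion; the AUC is reported
#' alongside). The span with the lowest Brier score wins; among candidates
#' whose Brier score lies within one bootstrap standard error of the best,
#' the smallest span is preferred, as it retains more parameter variation
#' over the landmark variable.
#'
#' @param x a `gla_cohort` (training data).
#' @param config a GLA [predictor_config()]; its kernel spec's span is
#'   overridden by each grid value.
#' @param grid numeric vector of candidate spans in (0, 1].
#' @param n_splits,n_boot,seed,boot_mode,grid_size cross-validation
#'   controls passed to [cross_validated_compare()].
#' @return A `span_selection` list: `grid`, `accuracy` (data.frame of span,
#'   brier, brier_se, auc), `selected_span`.
#' @export
select_span <- function(x, config, grid, n_splits = 2, n_boot = 100,
                        seed = 1, boot_mode = "predictions",
                        grid_size = NULL) {
  stopifnot(length(grid) >= 1, all(grid > 0), all(grid <= 1))
  grid <- sort(grid)
  rows <- vector("list", length(grid))
  errs <- character(length(grid))
  for (k in seq_along(grid)) {
    cfg <- config
    cfg$kernel_spec$span <- grid[k]
    cfg$kernel_spec$bandwidth <- NULL
    res <- tryCatch(
      cross_validated_compare(x, methods = list(gla = cfg), benchmark = cfg,
                              horizons = config$horizon, n_splits = n_splits,
                              n_boot = n_boot, seed = seed,
                              boot_mode = boot_mode, grid_size = grid_size),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs[k] <- conditionMessage(res)
      next
    }
    rows[[k]] <- data.frame(span = grid[k], brier = res$brier[1],
                            brier_se = if (n_boot > 0) res$brier_se[1]
                                       else NA_real_,
                            auc = res$auc[1])
  }
  acc <- do.call(rbind, rows)
  if (is.null(acc) || nrow(acc) == 0) {
    feas <- ""
    stop("every candidate span failed (sparse neighborhoods); ",
         "smallest errors were: ", paste(unique(errs[errs != ""]),
                                         collapse = " | "))
  }
  best <- which.min(acc$brier)
  tol <- if (is.na(acc$brier_se[best])) 0 else acc$brier_se[best]
  similar <- acc$brier <= acc$brier[best] + tol
  selected <- min(acc$span[similar])
  structure(list(grid = grid, accuracy = acc, selected_span = selected),
            class = "span_selection")
}

#' @export
print.span_selection <- function(x, ...) {
  cat("<span_selection> selected span:", x$selected_span, "\n")
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}
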