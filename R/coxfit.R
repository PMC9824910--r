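#' Control parameters for the weighted Cox fitter
#'
#' @param eps_loglik convergence threshold on the relative change of the
#'   weighted partial log-likelihood (default 1e-9).
#' @param eps_score convergence threshold on the Euclidean norm of the
#'   weighted score (default 1e-7).
#' @param max_iter maximum Newton-Raphson iterations (default 100).
#' @param max_halvings maximum step-halvings per iteration (default 20).
#' @param coef_bound norm bound beyond which a coefficient path is flagged
#'   as divergent (monotone likelihood; default 50).
#' @return A list of class `cox_control`.
#' @export
cox_control <- function(eps_loglik = 1e-9, eps_score = 1e-7, max_iter = 100,
                        max_halvings = 20, coef_bound = 50) {
  structure(list(eps_loglik = eps_loglik, eps_score = eps_score,
                 max_iter = max_iter, max_halvings = max_halvings,
                 coef_bound = coef_bound),
            class = "cox_control")
}

# weighted partial log-likelihood, score and information under Breslow
# handling of ties; rows must be sorted by increasing time.
# Returns list(loglik, score, imat).
cox_quantities <- function(time, event, Z, w, beta) {
  n <- length(time)
  p <- ncol(Z)
  eta <- drop(Z %*% beta)
  we <- w * exp(eta)
  # reverse cumulative sums give risk-set aggregates; map each row to the
  # first index of its tie group so tied rows share one risk set
  first <- match(time, time)
  rc0 <- rev(cumsum(rev(we)))[first]
  S1 <- matrix(0, n, p)
  for (j in seq_len(p)) {
    S1[, j] <- rev(cumsum(rev(we * Z[, j])))[first]
  }
  ev <- event == 1
  loglik <- sum(w[ev] * (eta[ev] - log(rc0[ev])))
  Zbar <- S1 / rc0
  score <- colSums(w[ev] * (Z[ev, , drop = FALSE] - Zbar[ev, , drop = FALSE]))
  imat <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      S2jk <- rev(cumsum(rev(we * Z[, j] * Z[, k])))[first]
      v <- sum(w[ev] * (S2jk[ev] / rc0[ev] - Zbar[ev, j] * Zbar[ev, k]))
      imat[j, k] <- v
      imat[k, j] <- v
    }
  }
  list(loglik = loglik, score = score, imat = imat, rc0 = rc0)
}

#' Fit a weighted Cox proportional hazards model to landmark rows
#'
#' Maximizes the weighted Cox partial log-likelihood under working
#' independence (repeated rows of one subject are treated as independent;
#' downstream uncertainty is handled by subject-level bootstrap). Ties in
#' the residual time are handled with the Breslow approximation, which
#' composes cleanly with arbitrary nonnegative weights. Covariates are
#' centered at their weighted means before optimization; coefficients are
#' reported on the original scale. The weighted Breslow cumulative baseline
#' hazard (relative to the centered covariates) is returned alongside.
#'
#' @param data a `landmark_dataset`, or any data.frame with columns
#'   `residual_time`, `event`, and the covariates.
#' @param weights a [compute_weights()] result, a numeric vector of
#'   nonnegative row weights, or `NULL` for unit weights.
#' @param covariates character vector of covariate names entering the
#'   linear predictor.
#' @param control a [cox_control()].
#' @return An object of class `local_cox_fit`: `coefficients`,
#'   `baseline` (data.frame of event times and cumulative baseline hazard),
#'   `center`, `converged`, `flag`, `iterations`, `loglik`, `score_norm`,
#'   `n_effective_events`, `dropped_covariates`.
#' @export
fit_weighted_cox <- function(data, weights = NULL, covariates,
                             control = cox_control()) {
  df <- as.data.frame(data)
  if (length(covariates) == 0) stop("covariate_subset must be nonempty")
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  w <- if (is.null(weights)) rep(1, nrow(df))
       else if (inherits(weights, "gla_weights")) weights$weights
       else as.numeric(weights)
  if (length(w) != nrow(df)) stop("weights length must match row count")
  if (any(w < 0)) stop("weights must be nonnegative")

  keep <- w > 0
  df <- df[keep, , drop = FALSE]
  w <- w[keep]
  if (nrow(df) == 0) stop("no positive-weight rows")
  n_events <- sum(w * (df$event == 1)) / max(w)
  # the weight scale is irrelevant to the weighted partial likelihood;
  # normalize to mean 1 so results are exactly scale-invariant
  w <- w / mean(w)
  if (!any(df$event == 1)) {
    stop("no events among positive-weight rows; cannot fit")
  }

  # drop covariates constant across positive-weight rows
  dropped <- character(0)
  for (nm in covariates) {
    if (length(unique(df[[nm]])) < 2) dropped <- c(dropped, nm)
  }
  if (length(dropped)) {
    warning("covariate(s) constant across positive-weight rows dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    covariates <- setdiff(covariates, dropped)
    # all constant: fall back to the null model (baseline hazard only)
  }

  ord <- order(df$residual_time)
  df <- df[ord, , drop = FALSE]
  w <- w[ord]
  time <- df$residual_time
  event <- df$event
  Z <- as.matrix(df[, covariates, drop = FALSE])
  center <- colSums(Z * w) / sum(w)
  Zc <- sweep(Z, 2, center)
  p <- ncol(Zc)

  beta <- rep(0, p)
  q <- cox_quantities(time, event, Zc, w, beta)
  loglik <- q$loglik
  converged <- p == 0
  flag <- "ok"
  iter <- 0
  while (p > 0) {
    iter <- iter + 1
    step <- tryCatch(solve(q$imat, q$score), error = function(e) NULL)
    if (is.null(step)) {
      flag <- "singular_information"
      break
    }
    lambda <- 1
    for (hv in 0:control$max_halvings) {
      beta_new <- beta + lambda * step
      q_new <- cox_quantities(time, event, Zc, w, beta_new)
      if (is.finite(q_new$loglik) && q_new$loglik >= loglik - 1e-12) break
      lambda <- lambda / 2
    }
    rel <- abs(q_new$loglik - loglik) / (abs(loglik) + 1e-300)
    beta <- beta_new
    loglik <- q_new$loglik
    q <- q_new
    score_norm <- sqrt(sum(q$score^2))
    if (sqrt(sum(beta^2)) > control$coef_bound) {
      flag <- "monotone_likelihood"
      break
    }
    if (rel < control$eps_loglik || score_norm < control$eps_score) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) {
      flag <- "max_iterations"
      break
    }
  }
  score_norm <- sqrt(sum(q$score^2))

  # weighted Breslow cumulative baseline hazard at distinct event times,
  # on the centered-covariate scale
  ev_idx <- which(event == 1)
  ev_times <- time[ev_idx]
  firstu <- !duplicated(ev_times)
  utimes <- ev_times[firstu]  # already sorted
  grp <- match(ev_times, utimes)
  dsum <- as.numeric(tapply(w[ev_idx], grp, sum))
  # rc0 at the first row of each tie group containing an event
  rc0_at <- q$rc0[ev_idx][firstu]
  cumhaz <- unname(cumsum(dsum / rc0_at))

  structure(
    list(coefficients = stats::setNames(beta, covariates),
         baseline = data.frame(time = unname(utimes), cumhaz = cumhaz,
                               row.names = NULL),
         center = stats::setNames(center, covariates),
         converged = converged, flag = flag, iterations = iter,
         loglik = loglik, score_norm = score_norm,
         n_effective_events = n_events,
         dropped_covariates = dropped),
    class = "local_cox_fit"
  )
}

#' @export
print.local_cox_fit <- function(x, ...) {
  cat("<local_cox_fit> ", length(x$coefficients), " coefficient(s), ",
      nrow(x$baseline), " baseline event time(s), ",
      if (x$converged) "converged" else paste0("NOT converged (", x$flag, ")"),
      " in ", x$iterations, " iteration(s)\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

# evaluate the cumulative baseline hazard (right-continuous step function)
eval_cumhaz <- function(fit, u) {
  idx <- findInterval(u, fit$baseline$time)
  ifelse(idx == 0, 0, fit$baseline$cumhaz[pmax(idx, 1)])
}

#' Predict the horizon-specific event probability from a local Cox fit
#'
#' Returns \eqn{p^* = 1 - \exp\{-\Lambda_0(\tau) e^{\beta^T (Z - c)}\}},
#' the model's predicted probability of the event within `horizon` time
#' units of the prediction visit, where \eqn{\Lambda_0} is the weighted
#' Breslow cumulative baseline hazard and c the covariate center.
#'
#' @param fit a `local_cox_fit`.
#' @param covariates named numeric vector (or single-row data.frame)
#'   containing every covariate of the fit.
#' @param horizon positive prediction horizon tau on the residual-time
#'   scale.
#' @param allow_unconverged predict from a non-converged fit (default
#'   `FALSE`).
#' @return A `risk_prediction`: list with `probability`, `horizon`,
#'   `query_covariates`, `extrapolated` (TRUE when `horizon` exceeds the
#'   largest residual event time seen by the fit).
#' @export
predict_risk <- function(fit, covariates, horizon,
                         allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "local_cox_fit"), horizon >= 0)
  if (!fit$converged && !allow_unconverged) {
    stop("fit did not converge (", fit$flag,
         "); pass allow_unconverged = TRUE to override")
  }
  if (is.data.frame(covariates)) {
    covariates <- covariates[1, vapply(covariates, is.numeric, logical(1)),
                             drop = FALSE]
  }
  z <- unlist(covariates)[names(fit$coefficients)]
  if (anyNA(z)) stop("covariates missing value(s) for: ",
                     paste(names(fit$coefficients)[is.na(z)], collapse = ", "))
  lp <- sum(fit$coefficients * (z - fit$center))
  p <- 1 - exp(-eval_cumhaz(fit, horizon) * exp(lp))
  extrap <- nrow(fit$baseline) == 0 || horizon > max(fit$baseline$time)
  if (extrap) {
    warning("horizon ", horizon, " exceeds the largest residual event time ",
            "in the fit; prediction is an extrapolation", call. = FALSE)
  }
  structure(list(probability = p, horizon = horizon,
                 query_covariates = z, extrapolated = extrap),
            class = "risk_prediction")
}

#' @export
print.risk_prediction <- function(x, ...) {
  cat("<risk_prediction> P(event within ", x$horizon, ") = ",
      signif(x$probability, 4),
      if (x$extrapolated) "  [extrapolated]" else "", "\n", sep = "")
  invisible(x)
}

# vectorized risk prediction over the rows of newdata (internal fast path
# used by the evaluation protocol); no extrapolation warnings
predict_risk_many <- function(fit, newdata, horizon) {
  Z <- as.matrix(newdata[, names(fit$coefficients), drop = FALSE])
  lp <- drop(sweep(Z, 2, fit$center) %*% fit$coefficients)
  1 - exp(-eval_cumhaz(fit, horizon) * exp(lp))
}

#' Serialize a local Cox fit to JSON
#'
#' @param fit a `local_cox_fit`.
#' @param path output path.
#' @export
write_cox_fit <- function(fit, path) {
  stopifnot(inherits(fit, "local_cox_fit"))
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         center = as.list(fit$center),
         baseline = fit$baseline,
         converged = fit$converged, flag = fit$flag,
         loglik = fit$loglik,
         n_effective_events = fit$n_effective_events),
    path, auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
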