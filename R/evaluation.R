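#' Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates G(t) = P(C > t) on the residual-time scale by flipping the
#' event indicator (a censoring becomes the "event") in a Kaplan-Meier fit,
#' one record per validation row (working independence).
#'
#' @param time residual follow-up times.
#' @param event event indicators (1 = clinical event, 0 = censored).
#' @return A `censoring_km` object; evaluate with [eval_censoring()].
#' @export
censoring_survival <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  structure(list(time = sf$time, surv = sf$surv), class = "censoring_km")
}

#' Evaluate the censoring survival function
#'
#' @param G a [censoring_survival()] result.
#' @param t evaluation time(s).
#' @param left take the left limit G(t-) (default `FALSE`).
#' @return G(t) or G(t-).
#' @export
eval_censoring <- function(G, t, left = FALSE) {
  stopifnot(inherits(G, "censoring_km"))
  tt <- if (left) t - 1e-12 else t
  idx <- findInterval(tt, G$time)
  ifelse(idx == 0, 1, G$surv[pmax(idx, 1)])
}

# IPCW weights shared by the AUC and Brier estimators.
# cases: residual_time <= tau & event, weight 1/G(T-);
# controls: residual_time > tau, weight 1/G(tau);
# censored before tau: weight 0.
ipcw_weights <- function(time, event, tau, G) {
  is_case <- time <= tau & event == 1
  is_control <- time > tau
  w <- numeric(length(time))
  if (any(is_case)) {
    g <- eval_censoring(G, time[is_case], left = TRUE)
    if (any(g <= 0)) {
      stop("censoring survival is 0 at an observed case time before tau = ",
           tau, "; IPCW weight undefined")
    }
    w[is_case] <- 1 / g
  }
  if (any(is_control)) {
    gtau <- eval_censoring(G, tau)
    if (gtau <= 0) {
      stop("censoring survival is 0 at tau = ", tau,
           "; IPCW weight undefined")
    }
    w[is_control] <- 1 / gtau
  }
  list(w = w, is_case = is_case, is_control = is_control)
}

#' Time-dependent AUC with inverse probability of censoring weighting
#'
#' Cumulative-case / dynamic-control discrimination at the horizon:
#' cases are records with an observed event within `horizon`, controls are
#' records still event-free beyond it. The AUC is the IPCW-weighted
#' probability that a randomly drawn case carries a higher predicted risk
#' than a randomly drawn control, with half credit for ties; with no
#' censoring it reduces to the empirical Mann-Whitney statistic.
#'
#' @param records data.frame with columns `residual_time`, `event`,
#'   `prediction`.
#' @param horizon prediction horizon tau.
#' @param G optional pre-computed [censoring_survival()]; defaults to the
#'   KM over `records`.
#' @return List with `auc`, `n_cases`, `n_controls` (IPCW-weighted sizes).
#' @export
time_dependent_auc <- function(records, horizon, G = NULL) {
  if (is.null(G)) G <- censoring_survival(records$residual_time, records$event)
  iw <- ipcw_weights(records$residual_time, records$event, horizon, G)
  if (!any(iw$is_case) || !any(iw$is_control)) {
    stop("AUC undefined: need at least one case and one control at tau = ",
         horizon)
  }
  p_case <- records$prediction[iw$is_case]
  w_case <- iw$w[iw$is_case]
  p_ctrl <- records$prediction[iw$is_control]
  w_ctrl <- iw$w[iw$is_control]

  # O(n log n) weighted Mann-Whitney: for each case, total control weight
  # strictly below its prediction plus half the tied control weight
  op <- order(p_ctrl)
  p_sort <- p_ctrl[op]
  w_sort <- w_ctrl[op]
  cw <- cumsum(w_sort)
  below_idx <- findInterval(p_case, p_sort, left.open = TRUE)  # p_sort < p_case
  upto_idx <- findInterval(p_case, p_sort)                     # p_sort <= p_case
  w_below <- ifelse(below_idx == 0, 0, cw[pmax(below_idx, 1)])
  w_upto <- ifelse(upto_idx == 0, 0, cw[pmax(upto_idx, 1)])
  w_tied <- w_upto - w_below
  num <- sum(w_case * (w_below + 0.5 * w_tied))
  list(auc = num / (sum(w_case) * sum(w_ctrl)),
       n_cases = sum(w_case), n_controls = sum(w_ctrl))
}

#' Time-dependent Brier score with inverse probability of censoring
#' weighting
#'
#' IPCW estimate of the mean squared error between the event status at the
#' horizon and the predicted probability,
#' \eqn{E(1\{T \le \tau\} - p^*)^2}: observed events before tau weighted by
#' 1/G(T-), event-free records beyond tau by 1/G(tau), records censored
#' before tau contribute weight 0. With no censoring this is the plain mean
#' squared error.
#'
#' @inheritParams time_dependent_auc
#' @return The Brier score (scalar).
#' @export
brier_score <- function(records, horizon, G = NULL) {
  if (is.null(G)) G <- censoring_survival(records$residual_time, records$event)
  iw <- ipcw_weights(records$residual_time, records$event, horizon, G)
  status <- as.numeric(records$residual_time <= horizon)
  sum(iw$w * (status - records$prediction)^2) / nrow(records)
}

# deterministic substream seeds below 2^31 derived from a master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Cross-validated comparison of prediction strategies
#'
#' Implements the half-split validation protocol: subjects are randomly
#' split into equal training and validation halves; every method is fitted
#' on the training half; horizon-specific risks are predicted at every
#' eligible validation visit (optionally restricted to strata such as
#' biomarker bands or visit-time bands); time-dependent AUC and Brier score
#' are computed with IPCW; subject-level bootstrap resampling of the
#' training and validation halves (independently) yields 95 percent
#' percentile confidence intervals; results are averaged over split
#' repetitions. Differences versus the benchmark are reported as the
#' relative difference for the Brier score and the absolute difference for
#' the AUC.
#'
#' @param x a `gla_cohort`.
#' @param methods named list of [predictor_config()]s to evaluate.
#' @param benchmark a [predictor_config()] used as comparator (conventionally
#'   the static prediction model).
#' @param horizons numeric vector of prediction horizons.
#' @param strata optional named list of predicate functions; each takes the
#'   validation landmark data.frame and returns a logical row filter
#'   (default: a single stratum of all eligible visits).
#' @param n_splits number of split repetitions (default 5).
#' @param n_boot bootstrap resamples per split (default 2000; 0 disables
#'   intervals).
#' @param seed master seed for splits and bootstrap.
#' @param boot_mode `"refit"` (models are refitted on each training
#'   resample; the default, matching the protocol) or `"predictions"`
#'   (labeled fast mode: fixed fits, resampling only the validation
#'   records, so intervals reflect evaluation noise only).
#' @param grid_size optional integer: evaluate GLA methods with the
#'   grid-precompute approximation at this many landmark-variable grid
#'   points (see [predict_gla_many()]); `NULL` refits per query.
#' @return data.frame of class `gla_evaluation`: one row per method x
#'   stratum x horizon with `auc`, `brier`, bootstrap CI bounds,
#'   `delta_rel_brier`, `delta_abs_auc` and their CI bounds, and weighted
#'   case/control counts.
#' @export
cross_validated_compare <- function(x, methods, benchmark, horizons,
                                    strata = NULL, n_splits = 5,
                                    n_boot = 2000, seed = 1,
                                    boot_mode = c("refit", "predictions"),
                                    grid_size = NULL) {
  stopifnot(inherits(x, "gla_cohort"), n_splits >= 1, n_boot >= 0)
  boot_mode <- match.arg(boot_mode)
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("'methods' must be a named list of predictor configs")
  }
  if (is.null(strata)) strata <- list(all = function(df) rep(TRUE, nrow(df)))
  split_seeds <- derive_seeds(seed, n_splits)
  ids <- x$subjects$subject_id
  all_methods <- c(methods, list(.benchmark = benchmark))

  per_split <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(split_seeds[s])
    train_ids <- sample(ids, floor(length(ids) / 2))
    valid_ids <- setdiff(ids, train_ids)
    train <- subset_cohort(x, train_ids)
    valid <- subset_cohort(x, valid_ids)
    valid_lm <- build_landmark_dataset(valid)

    fits <- lapply(all_methods, function(cfg)
      fit_method(train, cfg, grid_size = grid_size))
    preds <- lapply(fits, function(f) {
      pm <- vapply(horizons, function(tau) predict_method(f, valid_lm, tau),
                   numeric(nrow(valid_lm)))
      matrix(pm, nrow = nrow(valid_lm))
    })

    boot_seeds <- if (n_boot > 0) derive_seeds(split_seeds[s] + 1L, n_boot)
                  else integer(0)
    rows <- list()
    for (st in names(strata)) {
      keep <- strata[[st]](valid_lm)
      if (!any(keep)) {
        warning("stratum '", st, "' has no eligible validation visits in ",
                "split ", s, "; skipped", call. = FALSE)
        next
      }
      for (hi in seq_along(horizons)) {
        tau <- horizons[hi]
        stats_pt <- eval_methods_at(valid_lm, preds, hi, keep, tau,
                                    names(methods))
        boot <- NULL
        if (n_boot > 0) {
          boot <- matrix(NA_real_, n_boot, 4 * length(methods) + 2)
          for (b in seq_len(n_boot)) {
            set.seed(boot_seeds[b])
            bt_ids <- sample(train_ids, replace = TRUE)
            bv_ids <- sample(valid_ids, replace = TRUE)
            ridx <- resample_landmark_idx(valid_lm, bv_ids)
            vl <- valid_lm[ridx, , drop = FALSE]
            keep_b <- strata[[st]](vl)
            if (!any(keep_b)) next
            if (boot_mode == "refit") {
              bt <- resample_cohort(train, bt_ids)
              fits_b <- lapply(all_methods, function(cfg)
                fit_method(bt, cfg, grid_size = grid_size))
              preds_b <- lapply(fits_b, function(f)
                matrix(predict_method(f, vl, tau), ncol = 1))
            } else {
              # predictions are deterministic per validation row: reuse
              preds_b <- lapply(preds, function(pm)
                pm[ridx, hi, drop = FALSE])
            }
            sb <- tryCatch(
              eval_methods_at(vl, preds_b, 1, keep_b, tau, names(methods)),
              error = function(e) NULL)
            if (!is.null(sb)) {
              boot[b, ] <- unlist(sb[c("auc", "brier", "delta_rel_brier",
                                       "delta_abs_auc", "bench_auc",
                                       "bench_brier")])
            }
          }
        }
        for (mi in seq_along(methods)) {
          m <- names(methods)[mi]
          row <- data.frame(method = m, stratum = st, horizon = tau,
                            split = s,
                            auc = stats_pt$auc[mi],
                            brier = stats_pt$brier[mi],
                            delta_rel_brier = stats_pt$delta_rel_brier[mi],
                            delta_abs_auc = stats_pt$delta_abs_auc[mi],
                            benchmark_auc = stats_pt$bench_auc,
                            benchmark_brier = stats_pt$bench_brier,
                            n_cases = stats_pt$n_cases,
                            n_controls = stats_pt$n_controls,
                            n_records = sum(keep))
          if (n_boot > 0) {
            nm <- length(methods)
            ci <- function(col) stats::quantile(boot[, col],
                                               c(0.025, 0.975), na.rm = TRUE)
            se <- function(col) stats::sd(boot[, col], na.rm = TRUE)
            row$auc_lo <- ci(mi)[1]; row$auc_hi <- ci(mi)[2]
            row$brier_lo <- ci(nm + mi)[1]; row$brier_hi <- ci(nm + mi)[2]
            row$delta_rel_brier_lo <- ci(2 * nm + mi)[1]
            row$delta_rel_brier_hi <- ci(2 * nm + mi)[2]
            row$delta_abs_auc_lo <- ci(3 * nm + mi)[1]
            row$delta_abs_auc_hi <- ci(3 * nm + mi)[2]
            row$brier_se <- se(nm + mi)
            row$delta_rel_brier_se <- se(2 * nm + mi)
          }
          rows[[length(rows) + 1]] <- row
        }
      }
    }
    per_split[[s]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, per_split)
  # average point estimates and interval bounds across split repetitions
  num_cols <- setdiff(names(res), c("method", "stratum", "horizon", "split"))
  agg <- stats::aggregate(res[num_cols],
                          by = res[c("method", "stratum", "horizon")],
                          FUN = mean)
  agg$split <- NULL
  structure(agg, class = c("gla_evaluation", "data.frame"),
            n_splits = n_splits, n_boot = n_boot, boot_mode = boot_mode)
}

# point-estimate AUC/Brier for every method plus benchmark deltas on the
# filtered validation rows; preds is a list of matrices (rows x horizons)
eval_methods_at <- function(valid_lm, preds, hi, keep, tau, method_names) {
  recs <- data.frame(residual_time = valid_lm$residual_time[keep],
                     event = valid_lm$event[keep])
  G <- censoring_survival(recs$residual_time, recs$event)
  get <- function(nm) {
    recs$prediction <- preds[[nm]][keep, hi]
    a <- time_dependent_auc(recs, tau, G)
    list(auc = a$auc, brier = brier_score(recs, tau, G),
         n_cases = a$n_cases, n_controls = a$n_controls)
  }
  bench <- get(".benchmark")
  out <- list(auc = numeric(0), brier = numeric(0))
  for (nm in method_names) {
    m <- get(nm)
    out$auc <- c(out$auc, m$auc)
    out$brier <- c(out$brier, m$brier)
  }
  out$delta_rel_brier <- (out$brier - bench$brier) / bench$brier
  out$delta_abs_auc <- out$auc - bench$auc
  out$bench_auc <- bench$auc
  out$bench_brier <- bench$brier
  out$n_cases <- bench$n_cases
  out$n_controls <- bench$n_controls
  out
}

# bootstrap helpers: resample subjects with replacement, relabeling
# duplicates so cohort invariants (unique ids) keep holding
resample_cohort <- function(x, ids) {
  tag <- make.unique(ids, sep = "#")
  s_idx <- match(ids, x$subjects$subject_id)
  subjects <- x$subjects[s_idx, , drop = FALSE]
  subjects$subject_id <- tag
  vis <- lapply(seq_along(ids), function(k) {
    v <- x$visits[x$visits$subject_id == ids[k], , drop = FALSE]
    v$subject_id <- tag[k]
    v
  })
  cohort(subjects, do.call(rbind, vis), covariate_names = x$covariate_names,
         warn_no_time_covariate = FALSE)
}

resample_landmark_idx <- function(lm, ids) {
  by_subj <- split(seq_len(nrow(lm)), lm$subject_id)
  unlist(by_subj[ids], use.names = FALSE)
}
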