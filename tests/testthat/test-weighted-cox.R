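test_that("symmetric two-group data gives a zero coefficient", {
  # two groups with identical event/censoring patterns
  df <- data.frame(subject_id = as.character(1:8), visit_time = 0,
                   residual_time = rep(c(1, 2, 3, 4), 2),
                   event = rep(c(1, 1, 0, 1), 2),
                   z = rep(c(0, 1), each = 4))
  lm <- structure(df, covariate_names = "z", n_dropped = 0,
                  class = c("landmark_dataset", "data.frame"))
  fit <- fit_weighted_cox(lm, NULL, "z")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)
})

test_that("the fitter reproduces the frozen brute-force optimum on the toy dataset", {
  df <- data.frame(subject_id = as.character(1:8), visit_time = 0,
                   residual_time = c(2, 3, 5, 7, 8, 11, 12, 15),
                   event = c(1, 1, 0, 1, 1, 0, 1, 1),
                   z = c(0.5, -1, 0.3, 1.2, -0.7, 2, -1.5, 0.8))
  lm <- structure(df, covariate_names = "z", n_dropped = 0,
                  class = c("landmark_dataset", "data.frame"))
  fit <- fit_weighted_cox(lm, NULL, "z")
  # value from maximizing the enumerated partial likelihood with optimize()
  expect_equal(unname(fit$coefficients), -0.2803376010, tolerance = 1e-6)
  # and the loglik agrees with the naive enumeration at the optimum
  expect_equal(fit$loglik,
               naive_cox_loglik(fit$coefficients, df$residual_time,
                                df$event, df$z),
               tolerance = 1e-9)
})

test_that("duplicating rows while halving weights changes nothing", {
  lm <- random_cox_dataset(21)
  covs <- attr(lm, "covariate_names")
  f1 <- fit_weighted_cox(lm, NULL, covs)
  lm2 <- rbind(lm, lm)
  class(lm2) <- class(lm)
  f2 <- fit_weighted_cox(lm2, rep(0.5, nrow(lm2)), covs)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$baseline, f2$baseline, tolerance = 1e-8)
})

test_that("weight scaling and zero-weight rows are inert", {
  lm <- random_cox_dataset(22)
  covs <- attr(lm, "covariate_names")
  w <- runif(nrow(lm), 0.5, 2)
  f1 <- fit_weighted_cox(lm, w, covs)
  f2 <- fit_weighted_cox(lm, w * 17.3, covs)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$baseline$cumhaz, f2$baseline$cumhaz, tolerance = 1e-10)
  # junk rows with weight zero
  junk <- lm[sample(nrow(lm), 4), ]
  junk$residual_time <- junk$residual_time * 0.7 + 0.05
  junk$event <- 1
  lm3 <- rbind(lm, junk)
  class(lm3) <- class(lm)
  f3 <- fit_weighted_cox(lm3, c(w, rep(0, 4)), covs)
  expect_equal(f1$coefficients, f3$coefficients)
  expect_equal(f1$baseline, f3$baseline)
})

test_that("the analytic score vanishes at convergence", {
  for (seed in 31:35) {
    lm <- random_cox_dataset(seed, max_rows = 30)
    fit <- fit_weighted_cox(lm, NULL, attr(lm, "covariate_names"))
    expect_true(fit$converged)
    expect_lt(fit$score_norm, 1e-6)
  }
})

test_that("the fitter matches coxph with Breslow ties on random data", {
  for (seed in 41:50) {
    lm <- random_cox_dataset(seed, max_rows = 40)
    covs <- attr(lm, "covariate_names")
    fit <- fit_weighted_cox(lm, NULL, covs)
    fml <- stats::reformulate(covs,
                              response = "survival::Surv(residual_time, event)")
    cp <- suppressWarnings(
      survival::coxph(fml, data = lm, ties = "breslow",
                      control = survival::coxph.control(eps = 1e-11,
                                                        toler.chol = 1e-13,
                                                        iter.max = 100)))
    if (max(abs(coef(cp))) > 5) next  # monotone likelihood: no finite optimum
    expect_equal(unname(fit$coefficients), unname(coef(cp)),
                 tolerance = 1e-5)
    # Breslow cumulative baseline hazard: compare against basehaz at the
    # mean-centered scale used by coxph
    bh <- survival::basehaz(cp, centered = TRUE)
    shift <- exp(sum(coef(cp) * (cp$means - fit$center)))
    ours <- eval_cumhaz_for_test(fit, bh$time) * shift
    expect_equal(unname(ours), bh$hazard, tolerance = 1e-4)
  }
})

test_that("degenerate inputs are rejected or flagged", {
  lm <- random_cox_dataset(61)
  covs <- attr(lm, "covariate_names")
  expect_error(fit_weighted_cox(lm, NULL, character(0)), "nonempty")
  expect_error(fit_weighted_cox(lm, rep(0, nrow(lm)), covs),
               "no positive-weight rows")
  lm0 <- lm
  lm0$event <- 0
  expect_error(fit_weighted_cox(lm0, NULL, covs), "no events")
  # all covariates constant: warns and falls back to the null model
  lmc <- lm
  for (nm in covs) lmc[[nm]] <- 1
  expect_warning(fnull <- fit_weighted_cox(lmc, NULL, covs), "constant")
  expect_length(fnull$coefficients, 0)
  expect_true(fnull$converged)

  # perfectly separated data: monotone likelihood is flagged once the
  # coefficient path crosses the norm bound
  sep <- data.frame(subject_id = as.character(1:6), visit_time = 0,
                    residual_time = c(1, 2, 3, 10, 11, 12),
                    event = 1, z = c(1, 1, 1, 0, 0, 0))
  class(sep) <- c("landmark_dataset", "data.frame")
  fit <- fit_weighted_cox(sep, NULL, "z",
                          control = cox_control(coef_bound = 5))
  expect_false(fit$converged)
  expect_equal(fit$flag, "monotone_likelihood")
})

test_that("risk predictions follow the closed form and stay in [0, 1]", {
  lm <- random_cox_dataset(62, max_rows = 20)
  covs <- attr(lm, "covariate_names")
  fit <- fit_weighted_cox(lm, NULL, covs)
  q <- lm[1, ]
  # tau = 0 has zero cumulative hazard
  expect_equal(predict_risk(fit, q, 0)$probability, 0)
  # nondecreasing in tau, bounded in [0, 1]
  taus <- seq(0, max(lm$residual_time) * 1.1, length.out = 25)
  probs <- vapply(taus, function(tau)
    suppressWarnings(predict_risk(fit, q, tau))$probability, numeric(1))
  expect_true(all(diff(probs) >= 0))
  expect_true(all(probs >= 0 & probs <= 1))
  # extrapolation beyond the last event time is flagged
  expect_warning(p <- predict_risk(fit, q, max(lm$residual_time) * 2),
                 "extrapolation")
  expect_true(p$extrapolated)
})

test_that("a one-row dataset reproduces the textbook Breslow value", {
  # single subject, weight 1, one event at u = 2, z constant:
  # Lambda0(2) = 1 so the probability at tau = 2 is 1 - exp(-1)
  one <- data.frame(subject_id = "a", visit_time = 0, residual_time = 2,
                    event = 1, z = 0)
  class(one) <- c("landmark_dataset", "data.frame")
  expect_warning(fit <- fit_weighted_cox(one, NULL, "z"), "constant")
  expect_equal(fit$baseline, data.frame(time = 2, cumhaz = 1))
  expect_equal(predict_risk(fit, c(z = 0), 2)$probability,
               1 - exp(-1), tolerance = 1e-12)
  # beta = 0 closed form: cumhaz 0.3 gives 1 - exp(-0.3)
  fit0 <- fit
  fit0$baseline <- data.frame(time = 1, cumhaz = 0.3)
  expect_equal(suppressWarnings(predict_risk(fit0, c(z = 0), 1.5))$probability,
               1 - exp(-0.3), tolerance = 1e-12)
})
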