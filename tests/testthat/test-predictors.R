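test_that("the SPM uses exactly one baseline row per subject", {
  x <- simulate_cohort(test_sim_config(n = 120, seed = 31))
  cfg <- predictor_config("SPM", covariates = c("biomarker", "age", "z"),
                          horizon = 3)
  fit <- fit_spm(x, cfg)
  expect_true(fit$converged)
  base <- glandmark:::baseline_rows(x)
  expect_equal(nrow(base), nrow(x$subjects))
  # matches a direct unit-weight fit on the baseline rows (pooled fit
  # restricted to baseline)
  direct <- fit_weighted_cox(base, NULL, c("biomarker", "age", "z"))
  expect_identical(fit$coefficients, direct$coefficients)
})

test_that("GLA with full span and uniform kernel equals the pooled landmark fit", {
  x <- simulate_cohort(test_sim_config(n = 100, seed = 32))
  lm <- build_landmark_dataset(x)
  cfg <- predictor_config(
    "GLA", kernel_spec("biomarker", kernel = "uniform", span = 1),
    covariates = c("age", "z"), adjust_landmark_linear = TRUE, horizon = 3)
  q <- lm[7, ]
  p_local <- predict_gla(lm, cfg, q)
  pooled <- fit_weighted_cox(lm, NULL, c("age", "z", "biomarker"))
  p_pooled <- predict_risk(pooled, q, 3)
  expect_equal(p_local$probability, p_pooled$probability, tolerance = 1e-10)
  # the local coefficient on the landmark variable equals the pooled one
  expect_equal(attr(p_local, "fit")$coefficients[["biomarker"]],
               pooled$coefficients[["biomarker"]], tolerance = 1e-10)
})

test_that("SPM equals full-span GLA on a single-visit-per-subject cohort", {
  x <- simulate_cohort(test_sim_config(
    n = 150, seed = 33,
    visit_schedule = list(interval = 1, jitter = 0.1, max_visits = 1)))
  lm <- build_landmark_dataset(x)
  spm_cfg <- predictor_config("SPM", covariates = c("age", "z", "biomarker"),
                              horizon = 3)
  spm <- fit_spm(x, spm_cfg)
  gla_cfg <- predictor_config(
    "GLA", kernel_spec("biomarker", kernel = "uniform", span = 1),
    covariates = c("age", "z"), horizon = 3)
  q <- lm[3, ]
  p_gla <- predict_gla(lm, gla_cfg, q)
  p_spm <- predict_risk(spm, q, 3)
  expect_equal(p_gla$probability, p_spm$probability, tolerance = 1e-10)
})

test_that("GLA localized on time depends only on the visit-time distance", {
  x <- simulate_cohort(test_sim_config(n = 100, seed = 34))
  lm <- build_landmark_dataset(x)
  cfg <- predictor_config("GLA",
                          kernel_spec("time", kernel = "uniform", span = 0.5),
                          covariates = c("age", "z", "biomarker"),
                          horizon = 3)
  # classical landmark analysis: no linear adjustment of the landmark time
  expect_false(cfg$adjust_landmark_linear)
  q1 <- lm[1, ]; q1$visit_time <- 2
  q2 <- q1; q2$biomarker <- q2$biomarker + 10  # not a landmark variable
  p1 <- predict_gla(lm, cfg, q1)
  p2 <- predict_gla(lm, cfg, q2)
  expect_equal(attr(p1, "fit")$coefficients, attr(p2, "fit")$coefficients)
})

test_that("identical queries give identical predictions and row order is irrelevant", {
  x <- simulate_cohort(test_sim_config(n = 100, seed = 35))
  lm <- build_landmark_dataset(x)
  cfg <- predictor_config("GLA", kernel_spec("biomarker", span = 0.4),
                          covariates = c("age", "z"), horizon = 3)
  q <- lm[11, ]
  expect_equal(predict_gla(lm, cfg, q)$probability,
               predict_gla(lm, cfg, q)$probability)
  perm <- lm[sample(nrow(lm)), ]
  class(perm) <- class(lm)
  attr(perm, "covariate_names") <- attr(lm, "covariate_names")
  expect_equal(predict_gla(perm, cfg, q)$probability,
               predict_gla(lm, cfg, q)$probability, tolerance = 1e-10)
})

test_that("a null baseline covariate yields chance-level validation AUC", {
  # permuted outcome labels break any association at baseline
  x <- simulate_cohort(test_sim_config(n = 500, seed = 36))
  set.seed(99)
  perm <- sample(nrow(x$subjects))
  x$subjects$followup_time <- x$subjects$followup_time[perm]
  x$subjects$event <- x$subjects$event[perm]
  x$visits <- x$visits[x$visits$visit_time == 0, ]
  cfg <- predictor_config("SPM", covariates = c("biomarker", "age", "z"),
                          horizon = 3)
  fit <- fit_spm(x, cfg)
  expect_lt(abs(fit$coefficients[["biomarker"]]), 0.1)
  lm <- build_landmark_dataset(x)
  lm$prediction <- glandmark:::predict_risk_many(fit, lm, 3)
  a <- time_dependent_auc(lm, 3)
  expect_lt(abs(a$auc - 0.5), 0.08)
})

test_that("grid-precomputed GLA predictions track per-query refits", {
  x <- simulate_cohort(test_sim_config(n = 250, seed = 37))
  lm <- build_landmark_dataset(x)
  cfg <- predictor_config("GLA", kernel_spec("biomarker", span = 0.4),
                          covariates = c("age", "z"), horizon = 3)
  queries <- lm[seq(1, nrow(lm), by = 12), ]
  p_exact <- predict_gla_many(lm, cfg, queries, 3)
  p_grid <- predict_gla_many(lm, cfg, queries, 3, grid_size = 25)
  expect_lt(max(abs(p_exact - p_grid)), 0.02)
  expect_gt(cor(p_exact, p_grid), 0.999)
})

test_that("span selection returns the singleton and prefers small similar spans", {
  x <- simulate_cohort(test_sim_config(n = 200, seed = 38))
  cfg <- predictor_config("GLA", kernel_spec("biomarker", span = 0.5),
                          covariates = c("age", "z"), horizon = 3)
  sel1 <- select_span(x, cfg, grid = 1.0, n_splits = 1, n_boot = 0,
                      seed = 4, grid_size = 6)
  expect_equal(sel1$selected_span, 1.0)

  sel <- select_span(x, cfg, grid = c(0.3, 0.6, 1.0), n_splits = 1,
                     n_boot = 30, seed = 4, grid_size = 6)
  expect_true(sel$selected_span %in% c(0.3, 0.6, 1.0))
  expect_equal(nrow(sel$accuracy), 3)
  # the one-SE rule: every span with Brier within one SE of the best is
  # dominated by the selected (smallest such) span
  best <- which.min(sel$accuracy$brier)
  similar <- sel$accuracy$brier <= sel$accuracy$brier[best] +
    sel$accuracy$brier_se[best]
  expect_equal(sel$selected_span, min(sel$accuracy$span[similar]))
})

test_that("localized fits beat the pooled span under strong coefficient drift", {
  # cross-validated Brier at span 0.2 vs span 1.0 on drifted cohorts
  wins <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    x <- simulate_cohort(test_sim_config(n = 1000, seed = 700 + r))
    cfg <- predictor_config("GLA", kernel_spec("biomarker", span = 0.2),
                            covariates = c("age", "z"), horizon = 3)
    briers <- vapply(c(0.2, 1.0), function(g) {
      cfg$kernel_spec$span <- g
      res <- cross_validated_compare(x, methods = list(gla = cfg),
                                     benchmark = cfg, horizons = 3,
                                     n_splits = 1, n_boot = 0,
                                     seed = 700 + r, grid_size = 8)
      res$brier
    }, numeric(1))
    wins <- wins + (briers[1] < briers[2])
  }
  expect_gte(wins, 0.7 * reps)
})
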