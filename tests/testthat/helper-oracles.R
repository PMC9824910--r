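# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (double loops, generic optimizers) and share no code
# with the package internals.

# weighted Cox partial log-likelihood under Breslow ties, by direct
# enumeration of risk sets
naive_cox_loglik <- function(beta, time, event, Z, w = rep(1, length(time))) {
  Z <- as.matrix(Z)
  eta <- drop(Z %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      rs <- which(time >= time[i])
      ll <- ll + w[i] * (eta[i] - log(sum(w[rs] * exp(eta[rs]))))
    }
  }
  ll
}

# derivative-free maximization of the naive partial log-likelihood
oracle_cox_fit <- function(time, event, Z, w = rep(1, length(time))) {
  Z <- as.matrix(Z)
  f <- function(b) {
    val <- -naive_cox_loglik(b, time, event, Z, w)
    if (!is.finite(val)) 1e10 else val
  }
  if (ncol(Z) == 1) {
    stats::optimize(f, c(-8, 8), tol = 1e-12)$minimum
  } else {
    # Nelder-Mead with a restart for high-precision argmin
    o <- stats::optim(rep(0, ncol(Z)), f,
                      control = list(reltol = 1e-15, maxit = 10000))
    stats::optim(o$par, f,
                 control = list(reltol = 1e-15, maxit = 10000))$par
  }
}

# exhaustive pairwise Mann-Whitney statistic (no censoring)
brute_force_auc <- function(status, pred) {
  cases <- pred[status == 1]
  ctrls <- pred[status == 0]
  s <- 0
  for (pc in cases) {
    for (pk in ctrls) {
      s <- s + (pc > pk) + 0.5 * (pc == pk)
    }
  }
  s / (length(cases) * length(ctrls))
}

# small random survival datasets for fitter cross-checks
random_cox_dataset <- function(seed, max_rows = 12, p = NULL) {
  set.seed(seed)
  n <- sample(5:max_rows, 1)
  if (is.null(p)) p <- sample(1:2, 1)
  Z <- matrix(round(rnorm(n * p), 2), n, p,
              dimnames = list(NULL, paste0("z", seq_len(p))))
  df <- data.frame(subject_id = as.character(seq_len(n)),
                   visit_time = 0,
                   residual_time = round(rexp(n, 0.2), 3) + 0.01,
                   event = rbinom(n, 1, 0.75))
  if (sum(df$event) < 2) df$event[1:2] <- 1
  for (j in seq_len(p)) df[[colnames(Z)[j]]] <- Z[, j]
  structure(df, covariate_names = colnames(Z), n_dropped = 0,
            class = c("landmark_dataset", "data.frame"))
}

eval_cumhaz_for_test <- function(fit, u) glandmark:::eval_cumhaz(fit, u)

# three-subject toy cohort used across the I/O tests
toy_cohort <- function() {
  cohort(
    subjects = data.frame(subject_id = c("A", "B", "C"),
                          followup_time = c(10, 5, 4),
                          event = c(1, 0, 1)),
    visits = data.frame(
      subject_id = c("A", "A", "A", "B", "C", "C"),
      visit_time = c(0, 3, 7, 0, 0, 2),
      egfr = c(60, 50, 40, 55, 30, 25),
      age = c(50, 53, 57, 61, 70, 72)),
    warn_no_time_covariate = FALSE
  )
}

# fast simulator settings for functional tests
test_sim_config <- function(n = 300, seed = 42, ...) {
  simulator_config(n_subjects = n, seed = seed, grid_dt = 0.1, ...)
}
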