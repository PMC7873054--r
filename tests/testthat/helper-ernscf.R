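# Shared fixtures: small, fast cohort configurations built in code.

small_config <- function(seed = 1L, ...) {
  cohort_config(n_subjects = 6L, n_trials = 80L, seed = seed, ...)
}

# Counts-plus-design fixture for solver tests.
poisson_fixture <- function(n = 50L, p = 4L, seed = 1L,
                            beta = c(0.4, -0.3, rep(0, p - 2L)),
                            intercept = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rpois(n, exp(pmin(intercept + drop(X %*% beta), 20)))
  list(X = X, y = y, beta = beta, intercept = intercept)
}

# Penalized Poisson objective on the standardized scale, used by the
# brute-force oracles (independent of the solver's internals).
pen_objective <- function(b0, beta, Xs, y, lambda, alpha, pf = rep(1, ncol(Xs)),
                          offset = rep(0, length(y))) {
  eta <- b0 + drop(Xs %*% beta) + offset
  mean(exp(eta) - y * eta) +
    lambda * sum(pf * (alpha * abs(beta) + (1 - alpha) / 2 * beta^2))
}

standardize_cols <- function(X) {
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
}

# One seeded run of the parameter-recovery study; returns diagnostics.
run_recovery_seed <- function(seed) {
  cfg <- recovery_study_config(seed)
  co <- generate_cohort(cfg)
  X <- build_feature_matrix(cohort_condition_averages(co, "error"), co$times)
  scf <- score_ema_cohort(co)
  i <- match(as.integer(rownames(X)), scf$subject_id)
  y <- scf$scf_count[i]
  off <- log(scf$n_answered[i] / cfg$n_prompts)
  pipe <- fit_aenet(X, y, alpha_grid = c(0.75, 1), nlambda = 25L,
                    offset = off, folds = 5L, repeats = 3L,
                    seed = seed, gamma = 2)
  imp <- variable_importance(pipe$model, attr(X, "meta"))
  sup <- attr(co$truth, "support")
  topk <- head(imp, 4L)
  in_support <- paste(topk$electrode, topk$time_ms) %in%
    paste(sup$channel, sup$time_ms)
  list(pipe = pipe, importance = imp, support = sup,
       top_ok = nrow(topk) > 0 && all(in_support) && all(topk$estimate > 0))
}
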