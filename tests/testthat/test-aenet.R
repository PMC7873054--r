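test_that("input validation rejects malformed problems", {
  fx <- poisson_fixture()
  expect_error(fit_poisson_enet(fx$X, fx$y - 0.5, lambda = 0.1), "integer")
  expect_error(fit_poisson_enet(fx$X, -fx$y, lambda = 0.1), "nonnegative|integer")
  expect_error(fit_poisson_enet(fx$X, fx$y, alpha = 0, lambda = 0.1), "alpha")
  expect_error(fit_poisson_enet(fx$X, fx$y, lambda = -1), "nonnegative")
  expect_warning(
    fit_poisson_enet(cbind(fx$X, 1), fx$y, lambda = 0.1),
    "zero-variance")
})

test_that("a large penalty gives the intercept-only Poisson model", {
  fx <- poisson_fixture(seed = 2)
  f <- fit_poisson_enet(fx$X, fx$y, alpha = 0.75, lambda = 1e3)
  expect_identical(f$n_nonzero, 0L)
  expect_equal(f$intercept, log(mean(fx$y)), tolerance = 1e-10)
  expect_identical(nrow(f$importance), 0L)
})

test_that("the unpenalized fit matches the Poisson IRLS oracle", {
  # single feature, n = 50
  fx <- poisson_fixture(n = 50, p = 1, seed = 3, beta = 0.4)
  f <- fit_poisson_enet(fx$X, fx$y, alpha = 1, lambda = 0)
  g <- glm(fx$y ~ fx$X, family = poisson)
  expect_equal(unname(c(f$intercept, f$beta)), unname(coef(g)),
               tolerance = 1e-6)
  # several features, with offset
  fx2 <- poisson_fixture(n = 80, p = 3, seed = 4)
  off <- runif(80)
  f2 <- fit_poisson_enet(fx2$X, fx2$y, alpha = 0.5, lambda = 0, offset = off)
  g2 <- glm(fx2$y ~ fx2$X + offset(off), family = poisson)
  expect_equal(unname(c(f2$intercept, f2$beta)), unname(coef(g2)),
               tolerance = 1e-6)
})

test_that("the solver beats a brute-force grid on the penalized objective", {
  # the objective is convex, so a coarse grid plus local refinement finds
  # the global grid minimum
  grid_min <- function(Xs, y, lambda, alpha, lo, hi, step) {
    vals <- seq(lo, hi, by = step)
    grids <- do.call(expand.grid, rep(list(vals), ncol(Xs)))
    b0 <- log(mean(y))  # profile the intercept approximately via refit below
    obj <- apply(grids, 1L, function(b) {
      # profile intercept exactly for fixed slopes (1-d convex problem)
      eta0 <- drop(Xs %*% b)
      b0o <- log(mean(y)) - log(mean(exp(eta0)))
      pen_objective(b0o, b, Xs, y, lambda, alpha)
    })
    k <- which.min(obj)
    list(beta = as.numeric(grids[k, ]), obj = obj[k])
  }
  # p = 2 at the full 0.01 step
  fx <- poisson_fixture(n = 30, p = 2, seed = 5, beta = c(0.5, -0.4))
  Xs <- standardize_cols(fx$X)
  f <- fit_poisson_enet(Xs, fx$y, alpha = 0.75, lambda = 0.1, tol = 1e-10)
  obj_fit <- pen_objective(f$intercept, f$beta * apply(Xs, 2, function(c)
    sqrt(mean(c^2) - mean(c)^2)), Xs, fx$y, 0.1, 0.75)
  g <- grid_min(Xs, fx$y, 0.1, 0.75, -2, 2, 0.01)
  expect_lte(obj_fit, g$obj + 1e-8)
  # p = 3: coarse pass plus 0.01 refinement around the coarse optimum
  fx3 <- poisson_fixture(n = 30, p = 3, seed = 6, beta = c(0.5, -0.4, 0))
  Xs3 <- standardize_cols(fx3$X)
  f3 <- fit_poisson_enet(Xs3, fx3$y, alpha = 0.75, lambda = 0.1, tol = 1e-10)
  obj_fit3 <- pen_objective(f3$intercept, f3$beta * apply(Xs3, 2, function(c)
    sqrt(mean(c^2) - mean(c)^2)), Xs3, fx3$y, 0.1, 0.75)
  coarse <- grid_min(Xs3, fx3$y, 0.1, 0.75, -2, 2, 0.05)
  fine <- grid_min(Xs3, fx3$y, 0.1, 0.75,
                   max(-2, min(coarse$beta) - 0.06),
                   min(2, max(coarse$beta) + 0.06), 0.01)
  expect_lte(obj_fit3, min(coarse$obj, fine$obj) + 1e-8)
})

test_that("fits agree with an independent penalized-regression library", {
  skip_if_not_installed("glmnet")
  fx <- poisson_fixture(n = 60, p = 5, seed = 7,
                        beta = c(0.4, -0.3, 0.2, 0, 0))
  lam <- 0.05
  for (a in c(0.5, 1)) {
    mine <- fit_poisson_enet(fx$X, fx$y, alpha = a, lambda = lam)
    ref <- glmnet::glmnet(fx$X, fx$y, family = "poisson", alpha = a,
                          lambda = lam, thresh = 1e-12)
    expect_equal(unname(c(mine$intercept, mine$beta)),
                 as.numeric(coef(ref)), tolerance = 1e-4)
  }
  # per-feature penalty factors (reference rescales them to sum to p)
  pf <- c(2, 0.5, 1, 1, 1)
  pfn <- pf * length(pf) / sum(pf)
  mine <- fit_poisson_enet(fx$X, fx$y, alpha = 0.75, lambda = lam,
                           penalty_factors = pfn)
  ref <- glmnet::glmnet(fx$X, fx$y, family = "poisson", alpha = 0.75,
                        lambda = lam, penalty.factor = pf, thresh = 1e-12)
  expect_equal(unname(c(mine$intercept, mine$beta)),
               as.numeric(coef(ref)), tolerance = 1e-4)
})

test_that("the solution satisfies the KKT conditions", {
  fx <- poisson_fixture(n = 60, p = 6, seed = 8,
                        beta = c(0.4, -0.3, rep(0, 4)))
  lam <- 0.08; a <- 0.75
  f <- fit_poisson_enet(fx$X, fx$y, alpha = a, lambda = lam, tol = 1e-10)
  Xs <- standardize_cols(fx$X)
  xs <- apply(fx$X, 2, function(c) sqrt(mean(c^2) - mean(c)^2))
  bs <- f$beta * xs
  mu <- exp(f$intercept + drop(fx$X %*% f$beta))
  g <- drop(crossprod(Xs, mu - fx$y)) / length(fx$y)
  for (j in seq_along(bs)) {
    if (bs[j] == 0) {
      expect_lte(abs(g[j]), lam * a + 1e-6)
    } else {
      expect_lt(abs(g[j] + lam * a * sign(bs[j]) + lam * (1 - a) * bs[j]),
                1e-6)
    }
  }
  expect_lt(abs(mean(mu - fx$y)), 1e-8)  # intercept stationarity
})

test_that("the penalized objective is non-increasing over IRLS iterations", {
  for (s in 1:5) {
    fx <- poisson_fixture(n = 40, p = 8, seed = 20 + s,
                          beta = c(0.5, -0.4, 0.3, rep(0, 5)))
    f <- fit_poisson_enet(fx$X, fx$y, alpha = 0.75, lambda = 0.05)
    expect_true(all(diff(f$objective) <= 1e-10))
  }
})

test_that("identical columns receive equal coefficients when alpha < 1", {
  fx <- poisson_fixture(n = 80, p = 2, seed = 9, beta = c(0.5, 0))
  X <- cbind(fx$X[, 1], fx$X[, 1], fx$X[, 2])
  f <- fit_poisson_enet(X, fx$y, alpha = 0.5, lambda = 0.05, tol = 1e-10)
  expect_gt(abs(f$beta[1]), 0)
  expect_equal(unname(f$beta[1]), unname(f$beta[2]), tolerance = 1e-6)
})

test_that("importance ranks standardized coefficients with stable ties", {
  fx <- poisson_fixture(n = 60, p = 4, seed = 10)
  f <- fit_poisson_enet(fx$X, fx$y, alpha = 1, lambda = 0.02)
  imp <- f$importance
  expect_identical(nrow(imp), f$n_nonzero)
  expect_true(all(diff(abs(imp$estimate_std)) <= 1e-15))
  # constructed ranking: coefficients (0, -3, 2) on unit-variance features
  beta <- c(V1 = 0, V2 = -3, V3 = 2)
  tab <- ernscf:::.importance_table(beta)
  expect_identical(tab$feature, c("V2", "V3"))
})

test_that("adaptive penalty factors follow the reciprocal-coefficient rule", {
  fx <- poisson_fixture(seed = 11)
  f <- fit_poisson_enet(fx$X, fx$y, alpha = 0.75, lambda = 0.05)
  # raw factor for a zeroed coefficient is n before rescaling
  fake <- f
  fake$beta[] <- c(1, 1, 0, 0)
  pf <- adaptive_penalty_factors(fake, gamma = 1, n = 100)
  raw <- (abs(c(1, 1, 0, 0)) + 1 / 100)^(-1)  # zero coef -> raw factor 100
  expect_equal(raw[3], 100)
  expect_equal(unname(pf), raw / mean(raw))
  # symmetric coefficients give equal factors, rescaled to mean 1
  fake$beta[] <- c(1, 1, 1, 1)
  expect_equal(unname(adaptive_penalty_factors(fake, gamma = 1, n = 50)),
               rep(1, 4))
  # monotonicity: larger |beta| -> smaller factor, any gamma > 0
  fake$beta[] <- c(0.9, 0.1, 0.5, 0.2)
  for (g in c(0.5, 1, 2)) {
    pf <- adaptive_penalty_factors(fake, gamma = g, n = 50)
    expect_identical(order(pf), order(-abs(fake$beta)))
  }
  # all-zero initial model degrades to equal factors with a warning
  fake$beta[] <- 0
  expect_warning(pfz <- adaptive_penalty_factors(fake, gamma = 1, n = 50),
                 "zero")
  expect_equal(unname(pfz), rep(1, 4))
})

test_that("tuning selects the only cell of a singleton grid", {
  fx <- poisson_fixture(seed = 12)
  tn <- tune_poisson_enet(fx$X, fx$y, alpha_grid = 0.75,
                          lambda_path = 0.1, folds = 5, repeats = 2,
                          seed = 1)
  expect_identical(nrow(tn$grid), 1L)
  expect_equal(tn$best$alpha, 0.75)
  expect_equal(tn$best$lambda, 0.1)
})

test_that("duplicated-row CV with copy folds equals the apparent error", {
  fx <- poisson_fixture(n = 12, p = 2, seed = 13, beta = c(0.4, -0.2))
  Xd <- fx$X[rep(seq_len(12), times = 5), ]
  yd <- fx$y[rep(seq_len(12), times = 5)]
  foldid <- rep(1:5, each = 12)
  lam <- 0.05
  tn <- tune_poisson_enet(Xd, yd, alpha_grid = 0.75, lambda_path = lam,
                          foldid = foldid, tol = 1e-10)
  full <- fit_poisson_enet(Xd, yd, alpha = 0.75, lambda = lam, tol = 1e-10)
  expect_equal(tn$grid$mean_rmse, unname(full$metrics["rmse"]),
               tolerance = 1e-6)
})

test_that("tuning under the null prefers the sparse end of the path", {
  hits <- 0L
  nseeds <- 10L
  for (s in seq_len(nseeds)) {
    set.seed(400 + s)
    X <- matrix(rnorm(60 * 30), 60, 30)
    y <- rpois(60, 3)
    tn <- tune_poisson_enet(X, y, alpha_grid = c(0.5, 1), nlambda = 20,
                            folds = 5, repeats = 2, seed = s)
    if (tn$best$lambda_index <= 10) hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * nseeds)
})

test_that("gamma = 0 reduces the adaptive stage to the plain elastic net", {
  fx <- poisson_fixture(n = 60, p = 6, seed = 14,
                        beta = c(0.5, -0.4, rep(0, 4)))
  pipe <- fit_aenet(fx$X, fx$y, alpha_grid = c(0.75, 1), nlambda = 12,
                    folds = 5, repeats = 2, seed = 3, gamma = 0)
  expect_equal(unname(pipe$penalty_factors), rep(1, 6))
  ref <- fit_poisson_enet(fx$X, fx$y, alpha = pipe$model$alpha,
                          lambda = pipe$model$lambda)
  expect_equal(pipe$model$beta, ref$beta, tolerance = 1e-6)
})

test_that("adaptive factors separate true from null features", {
  ok <- 0L
  nseeds <- 8L
  for (s in seq_len(nseeds)) {
    fx <- poisson_fixture(n = 100, p = 10, seed = 40 + s,
                          beta = c(0.6, -0.5, rep(0, 8)))
    pipe <- fit_aenet(fx$X, fx$y, alpha_grid = c(0.75, 1), nlambda = 15,
                      folds = 5, repeats = 2, seed = s)
    pf <- pipe$penalty_factors
    sep <- mean(pf[3:10]) > max(pf[1:2])
    sparser <- pipe$model$n_nonzero <= pipe$enet_model$n_nonzero
    if (sep && sparser) ok <- ok + 1L
  }
  expect_gte(ok, 0.8 * nseeds)
})

test_that("the 0.632 bootstrap satisfies its identity and degenerate cases", {
  # constant outcome, intercept-only model: all errors are zero
  Xc <- matrix(rnorm(30), 30, 1)
  yc <- rep(4L, 30)
  b <- bootstrap_632(Xc, yc, alpha = 1, lambda = 1e3, B = 25, seed = 1)
  expect_equal(b$apparent, 0)
  expect_equal(b$oob, 0)
  expect_equal(b$err632, 0)
  expect_error(bootstrap_632(Xc, yc, lambda = 1, B = 0), "B")
  # the fixed-point identity err632 = 0.368 a + 0.632 oob
  fx <- poisson_fixture(n = 40, p = 3, seed = 15)
  b2 <- bootstrap_632(fx$X, fx$y, alpha = 0.75, lambda = 0.1, B = 40,
                      seed = 2)
  expect_equal(b2$err632, 0.368 * b2$apparent + 0.632 * b2$oob,
               tolerance = 1e-12)
  expect_true(b2$err632 >= min(b2$apparent, b2$oob) - 1e-12 &&
                b2$err632 <= max(b2$apparent, b2$oob) + 1e-12)
})

test_that("bootstrap error agrees with an independently coded oracle", {
  fx <- poisson_fixture(n = 60, p = 4, seed = 16,
                        beta = c(0.4, -0.3, 0, 0))
  lam <- 0.08
  got <- bootstrap_632(fx$X, fx$y, alpha = 0.75, lambda = lam, B = 120,
                       seed = 3)
  # second implementation, written independently of bootstrap_632
  set.seed(99)
  oob_oracle <- replicate(120, {
    take <- sample(60, replace = TRUE)
    held <- which(!(1:60 %in% take))
    if (length(held) == 0) return(NA_real_)
    fit <- fit_poisson_enet(fx$X[take, ], fx$y[take], alpha = 0.75,
                            lambda = lam)
    mu <- exp(fit$intercept + drop(fx$X[held, , drop = FALSE] %*% fit$beta))
    sqrt(mean((fx$y[held] - mu)^2))
  })
  app_oracle <- {
    fit <- fit_poisson_enet(fx$X, fx$y, alpha = 0.75, lambda = lam)
    unname(fit$metrics["rmse"])
  }
  oracle632 <- 0.368 * app_oracle + 0.632 * mean(oob_oracle, na.rm = TRUE)
  mc_band <- 3 * sd(oob_oracle, na.rm = TRUE) / sqrt(sum(!is.na(oob_oracle)))
  expect_lt(abs(got$err632 - oracle632), max(0.05, 3 * mc_band))
  expect_equal(got$apparent, app_oracle, tolerance = 1e-8)
})

test_that("variable importance maps features back to electrode and time", {
  meta <- data.frame(feature = c("Fz_62", "Fz_64", "FCz_50"),
                     electrode = c("Fz", "Fz", "FCz"),
                     time_ms = c(62, 64, 50))
  fake <- structure(list(beta = c(Fz_62 = 0, Fz_64 = -3, FCz_50 = 2),
                         importance = ernscf:::.importance_table(
                           c(Fz_62 = 0, Fz_64 = -3, FCz_50 = 2))),
                    class = "aenet_model")
  vi <- variable_importance(fake, meta)
  expect_identical(vi$electrode, c("Fz", "FCz"))
  expect_identical(vi$time_ms, c(64, 50))
  fake$importance <- ernscf:::.importance_table(c(Fz_62 = 0, Fz_64 = 0,
                                                  FCz_50 = 0))
  expect_identical(nrow(variable_importance(fake, meta)), 0L)
})
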