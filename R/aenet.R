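#' Poisson elastic net and adaptive elastic net
#'
#' `fit_poisson_enet()` fits a Poisson regression with an elastic-net
#' penalty by iteratively reweighted least squares with cyclic coordinate
#' descent on the working response. The objective is
#' \deqn{\frac{1}{n}\sum_i \left(\mu_i - y_i \eta_i\right) +
#'   \lambda \sum_j v_j \left(\alpha |\beta_j| +
#'   \frac{1-\alpha}{2}\beta_j^2\right),}
#' with \eqn{\eta_i = \beta_0 + x_i^\top\beta + o_i}, \eqn{\mu_i = e^{\eta_i}},
#' per-feature penalty factors \eqn{v_j \ge 0} and an unpenalized intercept.
#' Features are standardized internally (mean 0, 1/n-variance 1) and the
#' coefficients returned on the original scale.
#'
#' @param X numeric matrix of predictors (rows = observations).
#' @param y nonnegative integer response (counts).
#' @param alpha elastic-net mixing parameter in (0, 1]; 1 is the lasso.
#' @param lambda nonnegative penalty strength (single value).
#' @param penalty_factors nonnegative per-feature weights, recycled to
#'   `ncol(X)`; the default 1 penalizes all features equally.
#' @param offset optional per-row offset on the log scale (e.g. log exposure).
#' @param max_iter maximum outer IRLS iterations.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @return An object of class `"aenet_model"`: list with elements
#'   `intercept`, `beta` (original scale, named), `alpha`, `lambda`,
#'   `penalty_factors`, `offset`, `n_nonzero`, `metrics` (apparent `rmse`,
#'   `r2`, `mae` on the count scale), `importance` (nonzero features ranked
#'   by the absolute coefficient on the standardized scale, where features
#'   are comparable; `estimate` gives the original-scale value), `objective`
#'   (per-IRLS-iteration penalized objective trace) and `iterations`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4)
#' y <- rpois(50, exp(0.5 + 0.4 * X[, 1]))
#' fit <- fit_poisson_enet(X, y, alpha = 0.75, lambda = 0.05)
#' fit$importance
#' @export
fit_poisson_enet <- function(X, y, alpha = 0.75, lambda,
                             penalty_factors = 1, offset = NULL,
                             max_iter = 500L, tol = 1e-8) {
  chk <- .check_enet_inputs(X, y, alpha, penalty_factors, offset)
  fit <- .enet_path(chk$X, chk$y, alpha, lambda, chk$pf, chk$offset,
                    max_iter = max_iter, tol = tol, trace_obj = TRUE)
  .enet_model_at(fit, 1L, chk, alpha, lambda)
}

# Validate and pre-process inputs shared by the fitting entry points.
.check_enet_inputs <- function(X, y, alpha, penalty_factors, offset) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("X must be finite")
  if (nrow(X) < 2L) stop("need at least 2 rows")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must contain nonnegative integer counts")
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  pf <- rep_len(as.numeric(penalty_factors), ncol(X))
  if (any(!is.finite(pf)) || any(pf < 0))
    stop("penalty_factors must be finite and nonnegative")
  if (is.null(offset)) offset <- rep(0, nrow(X))
  if (length(offset) != nrow(X)) stop("offset length must equal nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  list(X = X, y = y, pf = pf, offset = as.numeric(offset))
}

# Standardize, call the compiled path solver, back-transform.
# `lambda` may be a decreasing vector (warm starts).
.enet_path <- function(X, y, alpha, lambda, pf, offset,
                       max_iter = 500L, tol = 1e-8, trace_obj = FALSE) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  zero_var <- xs <= .Machine$double.eps * 10
  if (any(zero_var)) {
    warning("zero-variance feature(s) forced to coefficient 0: ",
            paste(colnames(X)[zero_var], collapse = ", "))
    xs[zero_var] <- 1
  }
  Xs <- sweep(sweep(X, 2L, xm, "-"), 2L, xs, "/")
  Xs[, zero_var] <- 0
  pf2 <- pf
  pf2[zero_var] <- Inf  # never selected
  pf2[is.infinite(pf2)] <- 1e300
  lambda <- as.numeric(lambda)
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  raw <- cpp_poisson_enet_path(Xs, y, offset, alpha, lambda, pf2,
                               as.integer(max_iter), tol, trace_obj)
  if (any(raw$converged == 0L)) {
    bad <- which(raw$converged == 0L)
    stop(sprintf(
      "Poisson elastic net did not converge at lambda=%s after %d iterations",
      paste(signif(lambda[bad], 4), collapse = ", "), max_iter))
  }
  beta_std <- raw$beta
  beta_orig <- beta_std / xs
  b0_orig <- raw$b0 - colSums(beta_std * (xm / xs))
  list(b0 = b0_orig, beta = beta_orig, lambda = lambda,
       iterations = raw$iterations, objective = raw$objective,
       feature_names = colnames(X))
}

# Assemble an aenet_model for path entry k.
.enet_model_at <- function(path, k, chk, alpha, lambda) {
  beta <- path$beta[, k]
  names(beta) <- path$feature_names
  xs <- sqrt(colMeans(chk$X^2) - colMeans(chk$X)^2)
  eta <- path$b0[k] + drop(chk$X %*% beta) + chk$offset
  mu <- exp(pmin(eta, 30))
  m <- list(
    intercept = unname(path$b0[k]),
    beta = beta,
    alpha = alpha,
    lambda = lambda[k],
    penalty_factors = chk$pf,
    offset = chk$offset,
    n_nonzero = sum(beta != 0),
    metrics = c(rmse = sqrt(mean((chk$y - mu)^2)),
                r2 = 1 - sum((chk$y - mu)^2) / sum((chk$y - mean(chk$y))^2),
                mae = mean(abs(chk$y - mu))),
    objective = if (length(path$objective)) path$objective[[k]] else NULL,
    iterations = path$iterations[k]
  )
  m$importance <- .importance_table(beta, beta * xs)
  class(m) <- "aenet_model"
  m
}

# Nonzero coefficients ranked by the absolute coefficient on the
# standardized scale (the scale the model is estimated on, comparable
# across features); `estimate` stays on the original feature scale.
# Ties broken by column order.
.importance_table <- function(beta, beta_std = beta) {
  nz <- which(beta != 0)
  ord <- nz[order(-abs(beta_std[nz]), nz)]
  data.frame(feature = names(beta)[ord], estimate = unname(beta[ord]),
             estimate_std = unname(beta_std[ord]),
             stringsAsFactors = FALSE)
}

#' @export
print.aenet_model <- function(x, ...) {
  cat(sprintf(
    "Poisson elastic net: alpha=%g lambda=%g, %d nonzero of %d features\n",
    x$alpha, x$lambda, x$n_nonzero, length(x$beta)))
  cat(sprintf("apparent RMSE=%.4f R2=%.4f MAE=%.4f\n",
              x$metrics["rmse"], x$metrics["r2"], x$metrics["mae"]))
  invisible(x)
}

#' Predict expected counts from a fitted Poisson elastic net
#'
#' @param object an `aenet_model`.
#' @param newx matrix of predictors with the same columns as the training
#'   design.
#' @param offset optional log-scale offset for the new rows (default 0).
#' @param ... unused.
#' @return Numeric vector of predicted means \eqn{\exp(\eta)}.
#' @export
predict.aenet_model <- function(object, newx, offset = NULL, ...) {
  newx <- as.matrix(newx)
  if (is.null(offset)) offset <- rep(0, nrow(newx))
  eta <- object$intercept + drop(newx %*% object$beta) + offset
  exp(pmin(eta, 30))
}

#' Largest penalty with an all-zero solution
#'
#' Computes \eqn{\lambda_{max} = \max_j |x_j^\top (y - \bar y)| /
#' (n \alpha v_j)} at the intercept-only (offset-adjusted) fit, the
#' smallest penalty at which every coefficient is zero.
#'
#' @inheritParams fit_poisson_enet
#' @return A single positive number.
#' @export
lambda_max_poisson <- function(X, y, alpha = 0.75, penalty_factors = 1,
                               offset = NULL) {
  chk <- .check_enet_inputs(X, y, alpha, penalty_factors, offset)
  # intercept-only fit with offset: b0 = log(sum y / sum exp(offset))
  b0 <- log(max(sum(chk$y) / sum(exp(chk$offset)), 1e-10))
  mu <- exp(b0 + chk$offset)
  xm <- colMeans(chk$X)
  xs <- sqrt(colMeans(chk$X^2) - xm^2)
  xs[xs <= .Machine$double.eps * 10] <- Inf
  Xs <- sweep(sweep(chk$X, 2L, xm, "-"), 2L, xs, "/")
  g <- abs(drop(crossprod(Xs, chk$y - mu))) / nrow(chk$X)
  pf <- ifelse(chk$pf > 0, chk$pf, Inf)
  max(g / (alpha * pf)) * 1.000001
}

# Decreasing log-spaced lambda path.
.lambda_path <- function(lmax, nlambda, lambda_min_ratio) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Tune a Poisson elastic net by repeated k-fold cross-validation
#'
#' Evaluates a grid of mixing parameters and a per-alpha log-spaced lambda
#' path by repeated k-fold cross-validation, scoring held-out observations
#' with the root-mean-square error between observed counts and predicted
#' means. The selected cell minimizes the mean CV RMSE; exact ties are
#' broken toward the larger (sparser) lambda.
#'
#' @inheritParams fit_poisson_enet
#' @param alpha_grid vector of mixing values to evaluate.
#' @param nlambda number of lambda values per alpha.
#' @param lambda_min_ratio smallest lambda as a fraction of the largest;
#'   default 1e-4, or 0.01 when there are more features than rows (the
#'   nearly unpenalized deep end of the path is then degenerate).
#' @param lambda_path optional explicit lambda path (one decreasing vector
#'   used for every alpha; overrides `nlambda`).
#' @param folds number of CV folds.
#' @param repeats number of independent fold assignments.
#' @param seed integer seed controlling the fold assignments.
#' @param foldid optional integer vector of fold labels (length `nrow(X)`);
#'   when supplied, `repeats` is forced to 1 and `seed` is unused.
#' @return An object of class `"aenet_tune"`: `grid` (data frame with
#'   `alpha`, `lambda`, `lambda_index`, `mean_rmse`, `sd_rmse`), `best`
#'   (the selected row), `folds`, `repeats`, `seed`.
#' @export
tune_poisson_enet <- function(X, y,
                              alpha_grid = c(0.1, 0.25, 0.5, 0.75, 0.9, 1.0),
                              nlambda = 50L, lambda_min_ratio = NULL,
                              lambda_path = NULL,
                              penalty_factors = 1, offset = NULL,
                              folds = 5L, repeats = 10L, seed = 1L,
                              foldid = NULL,
                              max_iter = 500L, tol = 1e-6) {
  chk <- .check_enet_inputs(X, y, alpha_grid[1], penalty_factors, offset)
  n <- nrow(chk$X)
  if (n < folds) stop("need at least `folds` rows")
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (ncol(chk$X) > n) 0.01 else 1e-4

  if (!is.null(foldid)) {
    if (length(foldid) != n) stop("foldid length must equal nrow(X)")
    assignments <- list(as.integer(foldid))
    folds <- length(unique(foldid))
    repeats <- 1L
  } else {
    set.seed(seed)
    assignments <- lapply(seq_len(repeats), function(r) {
      sample(rep_len(seq_len(folds), n))
    })
  }

  paths <- lapply(alpha_grid, function(a) {
    if (!is.null(lambda_path)) sort(as.numeric(lambda_path), decreasing = TRUE)
    else .lambda_path(lambda_max_poisson(chk$X, chk$y, a, chk$pf, chk$offset),
                      nlambda, lambda_min_ratio)
  })

  grid <- NULL
  for (ai in seq_along(alpha_grid)) {
    a <- alpha_grid[ai]
    lams <- paths[[ai]]
    rmse_mat <- matrix(NA_real_, nrow = 0, ncol = length(lams))
    for (assign in assignments) {
      for (f in sort(unique(assign))) {
        test <- assign == f
        if (!any(test) || all(test)) stop("empty CV fold")
        fit <- .enet_path(chk$X[!test, , drop = FALSE], chk$y[!test], a,
                          lams, chk$pf, chk$offset[!test],
                          max_iter = max_iter, tol = tol)
        eta <- matrix(fit$b0, nrow = sum(test), ncol = length(lams),
                      byrow = TRUE) +
          chk$X[test, , drop = FALSE] %*% fit$beta + chk$offset[test]
        mu <- exp(pmin(eta, 30))
        rmse_mat <- rbind(rmse_mat,
                          sqrt(colMeans((chk$y[test] - mu)^2)))
      }
    }
    grid <- rbind(grid, data.frame(
      alpha = a, lambda = lams, lambda_index = seq_along(lams),
      mean_rmse = colMeans(rmse_mat),
      sd_rmse = apply(rmse_mat, 2L, sd)))
  }
  rownames(grid) <- NULL
  # minimal mean RMSE; ties go to the larger lambda (sparser model)
  best_i <- order(grid$mean_rmse, -grid$lambda)[1L]
  out <- list(grid = grid, best = grid[best_i, , drop = FALSE],
              folds = folds, repeats = repeats, seed = seed)
  class(out) <- "aenet_tune"
  out
}

#' @export
print.aenet_tune <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV (%d repeats), %d grid cells\n",
              x$folds, x$repeats, nrow(x$grid)))
  cat("selected: ")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Adaptive penalty factors from an initial fit
#'
#' Computes per-feature weights \eqn{v_j = (|\hat\beta_j| + 1/n)^{-\gamma}}
#' from the coefficients of an initial elastic-net fit and rescales them to
#' mean 1 so the lambda scale stays comparable between the plain and the
#' adaptive stage. Features shrunk to zero in the initial fit receive the
#' largest weights, pushing the adaptive stage toward sparser solutions
#' with less bias on the retained features.
#'
#' @param model an `aenet_model` from the initial (plain) elastic-net fit.
#' @param gamma positive adaptive exponent (default 1).
#' @param n sample size used for the \eqn{\epsilon = 1/n} guard.
#' @return Numeric vector of penalty factors with mean 1.
#' @export
adaptive_penalty_factors <- function(model, gamma = 1, n) {
  stopifnot(inherits(model, "aenet_model"), gamma >= 0, n >= 1)
  b <- abs(model$beta)
  if (all(b == 0)) {
    warning("all initial coefficients are zero; penalty factors set to 1 ",
            "(adaptive stage reduces to a plain elastic net)")
    return(rep(1, length(b)))
  }
  raw <- (b + 1 / n)^(-gamma)
  raw / mean(raw)
}

#' Two-stage adaptive elastic net pipeline
#'
#' Runs the full adaptive elastic net: (1) tune a plain Poisson elastic net
#' by repeated cross-validation, (2) fit at the selected cell, (3) derive
#' adaptive penalty factors from those coefficients, (4) re-tune alpha and
#' lambda with the factors fixed, and (5) fit the final model.
#'
#' @inheritParams tune_poisson_enet
#' @param gamma adaptive exponent passed to [adaptive_penalty_factors()].
#' @return An object of class `"aenet_pipeline"`: `enet_tune`, `enet_model`,
#'   `penalty_factors`, `aenet_tune`, `model` (the final `aenet_model`),
#'   plus the call parameters.
#' @export
fit_aenet <- function(X, y,
                      alpha_grid = c(0.1, 0.25, 0.5, 0.75, 0.9, 1.0),
                      nlambda = 50L, lambda_min_ratio = NULL,
                      offset = NULL, folds = 5L, repeats = 10L,
                      seed = 1L, gamma = 1,
                      max_iter = 500L, tol = 1e-6) {
  t1 <- tune_poisson_enet(X, y, alpha_grid = alpha_grid, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio,
                          offset = offset, folds = folds, repeats = repeats,
                          seed = seed, max_iter = max_iter, tol = tol)
  m1 <- fit_poisson_enet(X, y, alpha = t1$best$alpha, lambda = t1$best$lambda,
                         offset = offset, max_iter = max_iter, tol = tol)
  pf <- suppressWarnings(adaptive_penalty_factors(m1, gamma = gamma,
                                                  n = nrow(as.matrix(X))))
  t2 <- tune_poisson_enet(X, y, alpha_grid = alpha_grid, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio,
                          penalty_factors = pf, offset = offset,
                          folds = folds, repeats = repeats,
                          seed = seed + 1L, max_iter = max_iter, tol = tol)
  m2 <- fit_poisson_enet(X, y, alpha = t2$best$alpha, lambda = t2$best$lambda,
                         penalty_factors = pf, offset = offset,
                         max_iter = max_iter, tol = tol)
  out <- list(enet_tune = t1, enet_model = m1, penalty_factors = pf,
              aenet_tune = t2, model = m2, gamma = gamma, seed = seed)
  class(out) <- "aenet_pipeline"
  out
}

#' @export
print.aenet_pipeline <- function(x, ...) {
  cat("Adaptive elastic net pipeline\n")
  cat(sprintf(" stage 1 (plain): alpha=%g lambda=%.4g, %d nonzero\n",
              x$enet_model$alpha, x$enet_model$lambda,
              x$enet_model$n_nonzero))
  cat(sprintf(" stage 2 (adaptive, gamma=%g): alpha=%g lambda=%.4g, %d nonzero\n",
              x$gamma, x$model$alpha, x$model$lambda, x$model$n_nonzero))
  invisible(x)
}

#' 0.632 bootstrap internal validation
#'
#' Estimates prediction error as
#' \eqn{err_{.632} = 0.368\, err_{apparent} + 0.632\, \overline{err}_{oob}}:
#' for each of `B` bootstrap resamples (with replacement, size n) the model
#' is refit at fixed hyperparameters and its RMSE evaluated on the
#' out-of-bag rows. Resamples that leave no row out of bag contribute no
#' out-of-bag term and are counted in `n_skipped`.
#'
#' @inheritParams fit_poisson_enet
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @return An object of class `"bootstrap632"`: `B`, `apparent`, `oob`
#'   (mean out-of-bag RMSE), `err632`, `oob_values`, `n_skipped`.
#' @export
bootstrap_632 <- function(X, y, alpha = 0.75, lambda,
                          penalty_factors = 1, offset = NULL,
                          B = 1000L, seed = 1L,
                          max_iter = 500L, tol = 1e-7) {
  if (B < 1L) stop("B must be at least 1")
  chk <- .check_enet_inputs(X, y, alpha, penalty_factors, offset)
  n <- nrow(chk$X)
  full <- fit_poisson_enet(chk$X, chk$y, alpha = alpha, lambda = lambda,
                           penalty_factors = chk$pf, offset = chk$offset,
                           max_iter = max_iter, tol = tol)
  apparent <- unname(full$metrics["rmse"])
  set.seed(seed)
  oob_values <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) == 0L) next
    fit <- fit_poisson_enet(chk$X[idx, , drop = FALSE], chk$y[idx],
                            alpha = alpha, lambda = lambda,
                            penalty_factors = chk$pf,
                            offset = chk$offset[idx],
                            max_iter = max_iter, tol = tol)
    mu <- predict(fit, chk$X[oob, , drop = FALSE],
                  offset = chk$offset[oob])
    oob_values[b] <- sqrt(mean((chk$y[oob] - mu)^2))
  }
  n_skipped <- sum(is.na(oob_values))
  oob_mean <- mean(oob_values, na.rm = TRUE)
  out <- list(B = B, apparent = apparent, oob = oob_mean,
              err632 = 0.368 * apparent + 0.632 * oob_mean,
              oob_values = oob_values[!is.na(oob_values)],
              n_skipped = n_skipped, seed = seed)
  class(out) <- "bootstrap632"
  out
}

#' @export
print.bootstrap632 <- function(x, ...) {
  cat(sprintf(
    "0.632 bootstrap (B=%d, %d skipped): apparent=%.4f oob=%.4f err632=%.4f\n",
    x$B, x$n_skipped, x$apparent, x$oob, x$err632))
  invisible(x)
}

#' Variable importance mapped to electrode and time
#'
#' Ranks the nonzero coefficients of a fitted model by absolute value and
#' maps them back to their (electrode, time) labels using the feature
#' metadata of the design matrix the model was fit on.
#'
#' @param model an `aenet_model`.
#' @param feature_meta data frame with columns `feature`, `electrode`,
#'   `time_ms` in design-matrix column order, e.g. the `meta` attribute of
#'   [build_feature_matrix()] output.
#' @return Data frame with columns `electrode`, `time_ms`, `estimate`
#'   (original scale) and `estimate_std` (standardized scale), sorted by
#'   `|estimate_std|` descending (ties in column order). Empty when the
#'   model retains no feature.
#' @export
variable_importance <- function(model, feature_meta) {
  stopifnot(inherits(model, "aenet_model"))
  imp <- model$importance
  if (nrow(imp) == 0L) {
    return(data.frame(electrode = character(), time_ms = numeric(),
                      estimate = numeric(), estimate_std = numeric(),
                      stringsAsFactors = FALSE))
  }
  i <- match(imp$feature, feature_meta$feature)
  if (anyNA(i)) stop("feature metadata does not cover model features")
  data.frame(electrode = feature_meta$electrode[i],
             time_ms = feature_meta$time_ms[i],
             estimate = imp$estimate, estimate_std = imp$estimate_std,
             stringsAsFactors = FALSE)
}
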