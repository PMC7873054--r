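#' Negative-binomial regression of SCF counts on peak amplitude
#'
#' Fits a log-link NB2 GLM (variance \eqn{\mu + \mu^2/\theta}, dispersion
#' by maximum likelihood via [MASS::glm.nb()]) predicting per-subject SCF
#' counts from the individual peak amplitude, optionally with a
#' log-exposure offset for the number of answered prompts.
#'
#' @param peak_amplitudes numeric vector, one signed amplitude (µV) per
#'   subject (more negative = larger error-related component).
#' @param scf_counts nonnegative integer SCF counts, same length.
#' @param exposure optional positive exposures (e.g. answered prompts);
#'   when supplied, `log(exposure)` enters as an offset.
#' @return A list of class `"glm_result"`: `beta` (amplitude
#'   coefficient), `se`, `z` (Wald statistic `beta/se`), `p` (two-sided
#'   normal), `intercept`, `theta` (NB dispersion), `n`, `fit` (the
#'   underlying model object).
#' @export
negbin_glm_scf <- function(peak_amplitudes, scf_counts, exposure = NULL) {
  x <- as.numeric(peak_amplitudes)
  y <- as.numeric(scf_counts)
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 10L) stop("need at least 10 subjects")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("scf_counts must be nonnegative integers")
  if (sd(x) == 0) stop("zero-variance predictor")
  dat <- data.frame(y = y, x = x)
  fit <- if (is.null(exposure)) {
    MASS::glm.nb(y ~ x, data = dat)
  } else {
    if (any(exposure <= 0)) stop("exposure must be positive")
    dat$off <- log(exposure)
    MASS::glm.nb(y ~ x + offset(off), data = dat)
  }
  if (!fit$converged) stop("negative-binomial GLM did not converge (theta = ",
                           signif(fit$theta, 4), ")")
  cf <- summary(fit)$coefficients
  out <- list(beta = cf["x", "Estimate"], se = cf["x", "Std. Error"],
              z = cf["x", "z value"],
              p = 2 * pnorm(-abs(cf["x", "z value"])),
              intercept = cf["(Intercept)", "Estimate"],
              theta = fit$theta, n = length(y), fit = fit)
  class(out) <- "glm_result"
  out
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf(
    "NB GLM (n=%d, theta=%.2f): beta=%.4f, z=%.3f, p=%.4g\n",
    x$n, x$theta, x$beta, x$z, x$p))
  invisible(x)
}

# Trimmed mean and winsorized deviations.
.trim_mean <- function(x, trim) mean(x, trim = trim)
.winsorize <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  xs <- sort(x)
  lo <- xs[g + 1L]; hi <- xs[n - g]
  pmin(pmax(x, lo), hi)
}

# Yuen dependent-samples statistic: difference of trimmed means with a
# standard error from the winsorized variances/covariance.
.yuen_dep_stat <- function(x, y, trim) {
  n <- length(x)
  h <- n - 2L * floor(trim * n)
  wx <- .winsorize(x, trim); wy <- .winsorize(y, trim)
  d1 <- (n - 1) * var(wx)
  d2 <- (n - 1) * var(wy)
  d12 <- (n - 1) * cov(wx, wy)
  se <- sqrt((d1 + d2 - 2 * d12) / (h * (h - 1)))
  list(est = .trim_mean(x, trim) - .trim_mean(y, trim), se = se, h = h)
}

#' Bootstrap-t Yuen test for paired samples
#'
#' Robust paired location test: the point estimate is the difference of
#' the 20%-trimmed means; its standard error uses the winsorized
#' variances and covariance of the pair. The null reference distribution
#' is built by a bootstrap-t over paired resamples of the centered data,
#' giving a symmetric percentile-t confidence interval and p value.
#'
#' @param x,y paired numeric samples of equal length (at least 10).
#' @param trim trimming fraction in `[0, 0.5)` (default 0.2).
#' @param B bootstrap resamples (default 599).
#' @param seed optional integer seed.
#' @return A list of class `"yuen_result"`: `estimate` (trimmed-mean
#'   difference), `ci` (95% bootstrap-t interval), `p`, `se`, `trim`,
#'   `B`, `n`.
#' @export
yuen_boot_dep <- function(x, y, trim = 0.2, B = 599L, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 10L) stop("need at least 10 pairs")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  if (all(x == x[1]) && all(y == y[1]))
    stop("degenerate input: all values equal after trimming")

  s <- .yuen_dep_stat(x, y, trim)
  if (s$se == 0) {
    # all paired differences identical: the estimate has no sampling
    # variability, the interval collapses to a point
    p <- if (s$est == 0) 1 else 0
    out <- list(estimate = s$est, ci = c(s$est, s$est), p = p, se = 0,
                trim = trim, B = B, n = n)
    class(out) <- "yuen_result"
    return(out)
  }
  # center so that the bootstrap draws from a null world
  xc <- x - .trim_mean(x, trim)
  yc <- y - .trim_mean(y, trim)
  tstar <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sb <- .yuen_dep_stat(xc[idx], yc[idx], trim)
    tstar[b] <- if (sb$se > 0) sb$est / sb$se else 0
  }
  tcrit <- quantile(abs(tstar), 0.95, names = FALSE)
  tobs <- s$est / s$se
  out <- list(estimate = s$est,
              ci = c(s$est - tcrit * s$se, s$est + tcrit * s$se),
              p = mean(abs(tstar) >= abs(tobs)),
              se = s$se, trim = trim, B = B, n = n)
  class(out) <- "yuen_result"
  out
}

#' @export
print.yuen_result <- function(x, ...) {
  cat(sprintf("Yuen (trim=%g, B=%d, n=%d): Yt=%.3f, 95%% CI [%.3f, %.3f], p=%.4g\n",
              x$trim, x$B, x$n, x$estimate, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Pointwise error-versus-correct waveform tests
#'
#' Dependent-sample t tests at every (electrode, time point) of the
#' analysis window, comparing error and correct condition averages
#' across subjects, with a Bonferroni-corrected alpha. By default the
#' correction counts both electrodes jointly (m = electrodes x time
#' points, e.g. 2 x 175 = 350).
#'
#' @param error_averages,correct_averages lists (one element per subject)
#'   of channels x time matrices, same subjects in both.
#' @param times shared time axis in ms.
#' @param electrodes electrodes to test (default FCz and Fz).
#' @param window half-open window `[lo, hi)` in ms.
#' @param alpha familywise alpha (default 0.05).
#' @param per_electrode if `TRUE`, Bonferroni m counts each electrode's
#'   time points separately.
#' @return A list of class `"pointwise_tests"`: `table` (data frame
#'   `electrode`, `time_ms`, `t`, `p`, `significant`), `m`, `alpha`,
#'   `n`, and `runs` (contiguous significant windows per electrode).
#' @export
pointwise_error_vs_correct <- function(error_averages, correct_averages,
                                       times,
                                       electrodes = c("FCz", "Fz"),
                                       window = c(-50, 300),
                                       alpha = 0.05,
                                       per_electrode = FALSE) {
  n <- length(error_averages)
  if (n != length(correct_averages)) stop("subject lists differ in length")
  if (n < 3L) stop("need at least 3 subjects")
  tidx <- which(times >= window[1] & times < window[2])
  tsel <- times[tidx]
  # subject x (electrode-major feature) difference matrix
  D <- t(vapply(seq_len(n), function(s) {
    d <- error_averages[[s]][electrodes, tidx, drop = FALSE] -
      correct_averages[[s]][electrodes, tidx, drop = FALSE]
    as.vector(t(d))
  }, numeric(length(electrodes) * length(tidx))))
  mns <- colMeans(D)
  ses <- apply(D, 2L, sd) / sqrt(n)
  tval <- ifelse(ses > 0, mns / ses, 0)  # zero difference -> no evidence
  p <- 2 * pt(-abs(tval), df = n - 1)
  m_total <- length(tval)
  m <- if (per_electrode) length(tidx) else m_total
  sig <- p < alpha / m
  tab <- data.frame(electrode = rep(electrodes, each = length(tidx)),
                    time_ms = rep(tsel, times = length(electrodes)),
                    t = tval, p = p, significant = sig,
                    stringsAsFactors = FALSE)
  runs <- do.call(rbind, lapply(electrodes, function(e) {
    sub <- tab[tab$electrode == e, ]
    r <- rle(sub$significant)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(electrode = e, from_ms = sub$time_ms[starts[keep]],
               to_ms = sub$time_ms[ends[keep]],
               stringsAsFactors = FALSE)
  }))
  out <- list(table = tab, m = m, alpha = alpha, n = n, runs = runs)
  class(out) <- "pointwise_tests"
  out
}

#' @export
print.pointwise_tests <- function(x, ...) {
  cat(sprintf("Pointwise paired t tests: %d points, Bonferroni m=%d, %d significant\n",
              nrow(x$table), x$m, sum(x$table$significant)))
  if (!is.null(x$runs)) print(x$runs, row.names = FALSE)
  invisible(x)
}
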