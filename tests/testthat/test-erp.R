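make_epochs <- function(data, times, channels) {
  trials <- data.frame(condition = rep("error", dim(data)[3]),
                       congruency = "incongruent", accuracy = FALSE,
                       context = "gain")
  epoch_set(data, times, channels, trials)
}

test_that("baseline correction subtracts the pre-response window mean", {
  times <- seq(-500, 1000, by = 2)
  ch <- c("FCz", "Fz")
  # constant signal: correction zeroes everything
  data <- array(5, dim = c(2, length(times), 3))
  es <- baseline_correct(make_epochs(data, times, ch))
  expect_true(all(es$data == 0))
  # piecewise signal: baseline b inside the window, v elsewhere -> v - b
  v <- 3; b <- 1
  x <- ifelse(times >= -400 & times <= -200, b, v)
  data <- array(rep(x, each = 2), dim = c(2, length(times), 1))
  es <- baseline_correct(make_epochs(data, times, ch))
  outside <- times < -400 | times > -200
  expect_true(all(abs(es$data[, outside, 1] - (v - b)) < 1e-12))
  # random epochs: the corrected baseline mean is zero
  set.seed(1)
  data <- array(rnorm(2 * length(times) * 4), dim = c(2, length(times), 4))
  es <- baseline_correct(make_epochs(data, times, ch))
  idx <- times >= -400 & times <= -200
  expect_lt(max(abs(apply(es$data[, idx, , drop = FALSE], c(1, 3), mean))),
            1e-12)
  # window outside the epoch errors
  m <- matrix(rnorm(10), 1)
  expect_error(baseline_correct(m, window = c(-400, -200),
                                times = seq(0, 9)), "outside")
})

test_that("condition averaging is the arithmetic trial mean", {
  times <- seq(-500, 1000, by = 2)
  nt <- length(times)
  v <- matrix(rnorm(2 * nt), 2, nt)
  # single trial: identity
  es <- make_epochs(array(v, dim = c(2, nt, 1)), times, c("FCz", "Fz"))
  expect_equal(unname(condition_average(es, "error", min_trials = 1)), v,
               ignore_attr = TRUE)
  # v and -v: zero
  es2 <- make_epochs(array(c(v, -v), dim = c(2, nt, 2)), times, c("FCz", "Fz"))
  avg <- condition_average(es2, "error", min_trials = 1)
  expect_lt(max(abs(avg)), 1e-12)
  # linearity in the data
  es3 <- es2
  es3$data <- es3$data * 3
  expect_equal(unname(condition_average(es3, "error", min_trials = 1)),
               unname(3 * avg), ignore_attr = TRUE)
  # too few trials is a typed error
  expect_error(condition_average(es2, "error", min_trials = 6),
               class = "ernscf_too_few_trials")
  expect_identical(attr(condition_average(es2, "error", min_trials = 2),
                        "n_trials"), 2L)
})

test_that("feature matrix has electrode-major columns and the stated size", {
  times <- seq(-500, 1000, by = 2)
  avgs <- lapply(1:3, function(i) {
    m <- matrix(rnorm(23 * length(times)), 23, length(times))
    rownames(m) <- flanker_cluster_channels()
    m
  })
  names(avgs) <- 1:3
  X <- build_feature_matrix(avgs, times)
  expect_identical(dim(X), c(3L, 4025L))     # 23 electrodes x 175 samples
  meta <- attr(X, "meta")
  expect_identical(nrow(meta), 4025L)
  # electrode-major: first 175 columns all belong to the first electrode
  expect_true(all(meta$electrode[1:175] == flanker_cluster_channels()[1]))
  expect_identical(meta$time_ms[1:3], c(-50, -48, -46))
  # half-open window: 300 ms excluded, 298 included
  expect_identical(max(meta$time_ms), 298)
  # values map back to the source waveforms
  expect_equal(unname(X[2, "Fz_-50"]),
               unname(avgs[[2]]["Fz", which(times == -50)]))
  # a 2-electrode, [0, 10) window gives 2 x 5 columns
  X2 <- build_feature_matrix(avgs, times, electrodes = c("FCz", "Fz"),
                             window = c(0, 10))
  expect_identical(ncol(X2), 10L)
  # missing channel is named in the error
  avgs2 <- lapply(avgs, function(m) m[-2, ])
  expect_error(build_feature_matrix(avgs2, times), "FCz")
})

test_that("difference features equal error minus correct features", {
  co <- generate_cohort(small_config(seed = 19))
  Xe <- build_feature_matrix(cohort_condition_averages(co, "error"), co$times)
  Xc <- build_feature_matrix(cohort_condition_averages(co, "correct"), co$times)
  Xd <- build_feature_matrix(cohort_condition_averages(co, "difference"),
                             co$times, condition = "difference")
  expect_equal(unclass(Xd), unclass(Xe) - unclass(Xc),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("peak detection finds a constructed component and flags fallback", {
  times <- seq(-500, 1000, by = 2)
  ch <- c("FCz", "Fz", "F1", "F2")
  g <- -exp(-(times - 50)^2 / (2 * 15^2))
  m <- matrix(rep(g, each = 4), 4, length(times), dimnames = list(ch, NULL))
  pk <- detect_ern_peak(m, times)
  expect_identical(pk$latency_ms, 50)
  expect_false(pk$fallback)
  expect_lt(pk$amplitude, -0.9)
  # monotone waveform falls back to the window edge with a flag
  m2 <- matrix(rep(-times, each = 4), 4, length(times),
               dimnames = list(ch, NULL))
  pk2 <- detect_ern_peak(m2, times)
  expect_true(pk2$fallback)
  expect_identical(pk2$latency_ms, 150)
  # flat waveform errors
  m3 <- matrix(0, 4, length(times), dimnames = list(ch, NULL))
  expect_error(detect_ern_peak(m3, times), "flat")
})

test_that("noise-free cohorts give back the configured latency", {
  cfg <- small_config(noise_sd = 0, jitter_sd_ms = 0, seed = 3)
  co <- generate_cohort(cfg)
  step <- 1000 / cfg$sampling_rate
  for (s in co$subjects) {
    m <- s$averages$error
    rownames(m) <- co$channels
    pk <- detect_ern_peak(baseline_correct(m, times = co$times), co$times)
    expect_lte(abs(pk$latency_ms - cfg$ern_latency_ms), step)
  }
})

test_that("split-half reliability is 1 without noise and high at defaults", {
  cfg <- cohort_config(n_subjects = 12, noise_sd = 0, jitter_sd_ms = 0,
                       seed = 4)
  co <- generate_cohort(cfg)
  r <- eeg_split_half_reliability(co, "error")
  expect_gt(r$r_sb, 1 - 1e-6)

  # across seeds at study-scale trial counts the corrected reliability
  # stays in the band the generator was calibrated for
  rs <- sapply(1:6, function(s) {
    co <- generate_cohort(cohort_config(n_subjects = 40, seed = 100 + s))
    eeg_split_half_reliability(co, "error")$r_sb
  })
  expect_true(all(rs > 0.8 & rs <= 1))
})

test_that("pure-noise cohorts have reliabilities centered near zero", {
  # r_sb = 2r/(1+r) is left-skewed around r = 0, so the center is
  # assessed with the median
  rs <- sapply(1:9, function(s) {
    co <- generate_cohort(cohort_config(n_subjects = 25, n_trials = 120,
                                        ern_mu = 0, ern_sigma = 1e-6,
                                        crn_ratio = 0, seed = 200 + s))
    eeg_split_half_reliability(co, "error")$r_sb
  })
  expect_lt(abs(median(rs)), 0.4)
})

test_that("feature matrices round-trip through CSV bit-exactly", {
  co <- generate_cohort(small_config(seed = 6))
  X <- build_feature_matrix(cohort_condition_averages(co, "error"), co$times)
  path <- file.path(tempdir(), "features.csv")
  write_feature_matrix(X, path)
  X2 <- read_feature_matrix(path)
  expect_identical(unclass(X)[, ], unclass(X2)[, ])
  expect_equal(attr(X, "meta"), attr(X2, "meta"))
  unlink(c(path, paste0(path, ".json")))
})

test_that("epoch sets round-trip through their directory format", {
  co <- generate_cohort(cohort_config(n_subjects = 1, n_trials = 12, seed = 8),
                        keep_epochs = TRUE)
  es <- co$subjects[[1]]$epochs
  dir <- file.path(tempdir(), "epochs-rt")
  write_epochs(es, dir)
  es2 <- read_epochs(dir)
  expect_identical(es$data[, , ], es2$data[, , ])
  expect_equal(es$times, es2$times)
  expect_identical(es$channels, es2$channels)
  expect_equal(es$trials, es2$trials)
  unlink(dir, recursive = TRUE)
})
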