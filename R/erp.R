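#' Response-locked epoch container
#'
#' @param data numeric array, channels x time x trials, in µV.
#' @param times time axis in ms relative to the response; strictly
#'   increasing with a constant step of `1000/sampling_rate`.
#' @param channels unique channel labels (length `dim(data)[1]`).
#' @param trials data frame with one row per trial (columns such as
#'   `condition`, `congruency`, `accuracy`, `context`).
#' @return A validated list of class `"epoch_set"`.
#' @export
epoch_set <- function(data, times, channels, trials) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1] != length(channels)) stop("channel count mismatch")
  if (dim(data)[2] != length(times)) stop("time axis length mismatch")
  if (dim(data)[3] != nrow(trials)) stop("trial count mismatch")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)
    stop("times must be strictly increasing with a constant step")
  dimnames(data) <- list(channels, NULL, NULL)
  out <- list(data = data, times = times, channels = channels,
              trials = trials)
  class(out) <- "epoch_set"
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d channels x %d samples x %d trials, [%g, %g] ms\n",
              length(x$channels), length(x$times), nrow(x$trials),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Baseline-correct epochs or an averaged waveform
#'
#' Subtracts, per channel (and per trial for epoch sets), the mean
#' amplitude over the pre-response baseline window, by default
#' `[-400, -200]` ms.
#'
#' @param x an `epoch_set`, or a channels x time matrix (an averaged
#'   waveform).
#' @param window baseline window in ms (closed interval).
#' @param times time axis, required when `x` is a matrix.
#' @return Object of the same shape as `x`.
#' @export
baseline_correct <- function(x, window = c(-400, -200), times = NULL) {
  if (inherits(x, "epoch_set")) {
    idx <- .window_index(x$times, window)
    bl <- colMeans(aperm(x$data[, idx, , drop = FALSE], c(2, 1, 3)))
    dims <- dim(x$data)
    x$data <- x$data - aperm(array(bl, c(dims[1], dims[3], dims[2])),
                             c(1, 3, 2))
    return(x)
  }
  idx <- .window_index(times, window)
  x - rowMeans(x[, idx, drop = FALSE])
}

.window_index <- function(times, window) {
  if (is.null(times)) stop("times must be supplied")
  if (window[1] < min(times) || window[2] > max(times))
    stop(sprintf("window [%g, %g] ms lies outside the epoch [%g, %g] ms",
                 window[1], window[2], min(times), max(times)))
  which(times >= window[1] & times <= window[2])
}

#' Average epochs of one condition
#'
#' Arithmetic mean over the trials whose `condition` column matches.
#' Subjects contributing fewer than `min_trials` matching trials are
#' rejected (error of class `"ernscf_too_few_trials"`), so upstream
#' callers can exclude them from the feature matrix.
#'
#' @param epochs an `epoch_set`.
#' @param condition condition label to select (e.g. `"error"`).
#' @param min_trials minimum trial count required (default 6, common
#'   practice for stable error-trial averages).
#' @return channels x time matrix with attributes `n_trials` and `times`.
#' @export
condition_average <- function(epochs, condition, min_trials = 6L) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$trials$condition == condition)
  if (length(idx) < min_trials) {
    stop(structure(class = c("ernscf_too_few_trials", "error", "condition"),
                   list(message = sprintf(
                     "only %d '%s' trials (minimum %d)", length(idx),
                     condition, min_trials), call = sys.call(-1))))
  }
  avg <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2L)
  rownames(avg) <- epochs$channels
  attr(avg, "n_trials") <- length(idx)
  attr(avg, "times") <- epochs$times
  avg
}

#' Build the subjects x (electrode, time) feature matrix
#'
#' Flattens per-subject averaged waveforms into the design matrix of the
#' penalized regression: one column per (electrode, time point) pair over
#' the analysis window. The window is half-open, `[-50, 300)` ms by
#' default, which at 500 Hz (2 ms steps) yields exactly 175 samples and
#' 23 x 175 = 4,025 columns. Columns are electrode-major (all time points
#' of the first electrode, then the second), time ascending; this order
#' is fixed because penalty-factor vectors and importance tables index
#' into it.
#'
#' @param averages named list (one element per subject) of channels x
#'   time matrices, all sharing `times` and channel labels.
#' @param times shared time axis in ms.
#' @param electrodes electrode subset and order (default the 23-electrode
#'   cluster).
#' @param window half-open analysis window `[lo, hi)` in ms.
#' @param condition tag stored with the matrix (`"error"`, `"correct"`,
#'   `"difference"`).
#' @return Numeric matrix (class `"feature_matrix"`) with rownames from
#'   `averages` and colnames `"<electrode>_<time>"`; attributes `meta`
#'   (data frame `feature`, `electrode`, `time_ms`), `condition`,
#'   `window`.
#' @export
build_feature_matrix <- function(averages, times,
                                 electrodes = flanker_cluster_channels(),
                                 window = c(-50, 300),
                                 condition = "error") {
  stopifnot(length(averages) >= 1L)
  tidx <- which(times >= window[1] & times < window[2])
  if (length(tidx) == 0L) stop("empty analysis window")
  first <- averages[[1]]
  missing <- setdiff(electrodes, rownames(first))
  if (length(missing))
    stop("missing cluster channel(s): ", paste(missing, collapse = ", "))
  tsel <- times[tidx]
  meta <- data.frame(
    feature = as.vector(vapply(electrodes, function(e)
      sprintf("%s_%g", e, tsel), character(length(tsel)))),
    electrode = rep(electrodes, each = length(tsel)),
    time_ms = rep(tsel, times = length(electrodes)),
    stringsAsFactors = FALSE)
  X <- t(vapply(averages, function(a) {
    as.vector(t(a[electrodes, tidx, drop = FALSE]))
  }, numeric(nrow(meta))))
  colnames(X) <- meta$feature
  if (!is.null(names(averages))) rownames(X) <- names(averages)
  attr(X, "meta") <- meta
  attr(X, "condition") <- condition
  attr(X, "window") <- window
  class(X) <- c("feature_matrix", class(X))
  X
}

#' Individual peak of the error-related component
#'
#' Averages the waveform over the peak electrodes (FCz, Fz, F1, F2 by
#' default), finds the most negative interior local minimum within the
#' search window (falling back, with a flag, to the window minimum when
#' the waveform is monotone there), and scores the mean amplitude over a
#' 20 ms window centered on the peak.
#'
#' @param avg channels x time matrix (an averaged waveform, typically
#'   baseline-corrected).
#' @param times time axis in ms.
#' @param electrodes electrodes averaged before peak search.
#' @param search_window search interval in ms (default `[0, 150]`,
#'   containing the canonical 50-100 ms component).
#' @param half_width half of the amplitude window in ms (default 10).
#' @return List of class `"peak_measure"`: `latency_ms`, `amplitude`
#'   (mean µV over peak ± `half_width`), `fallback` (logical).
#' @export
detect_ern_peak <- function(avg, times,
                            electrodes = c("FCz", "Fz", "F1", "F2"),
                            search_window = c(0, 150), half_width = 10) {
  missing <- setdiff(electrodes, rownames(avg))
  if (length(missing))
    stop("missing electrode(s): ", paste(missing, collapse = ", "))
  w <- colMeans(avg[electrodes, , drop = FALSE])
  idx <- .window_index(times, search_window)
  v <- w[idx]
  if (max(v) - min(v) < .Machine$double.eps * 100)
    stop("flat waveform: no peak")
  interior <- which(diff(sign(diff(v))) > 0) + 1L  # local minima
  fallback <- length(interior) == 0L
  k <- if (fallback) which.min(v) else interior[which.min(v[interior])]
  peak_t <- times[idx[k]]
  if (peak_t - half_width < min(times) || peak_t + half_width > max(times))
    stop("amplitude window extends beyond the epoch")
  amp_idx <- which(times >= peak_t - half_width & times <= peak_t + half_width)
  out <- list(latency_ms = peak_t, amplitude = mean(w[amp_idx]),
              electrodes = electrodes, fallback = fallback)
  class(out) <- "peak_measure"
  out
}

#' @export
print.peak_measure <- function(x, ...) {
  cat(sprintf("peak at %g ms, mean amplitude %.3f uV (%s)%s\n",
              x$latency_ms, x$amplitude,
              paste(x$electrodes, collapse = "/"),
              if (x$fallback) " [window-edge fallback]" else ""))
  invisible(x)
}

#' Odd-even split-half reliability of the peak amplitude
#'
#' Splits each subject's trials of one condition by parity of their
#' within-condition order, averages each half, baseline-corrects, scores
#' the individual peak amplitude per half ([detect_ern_peak()]),
#' correlates the half amplitudes across subjects and applies the
#' Spearman-Brown correction. Works from the `averages` half-waveforms
#' stored by [generate_cohort()] or from per-subject `epoch_set`s.
#'
#' @param cohort a `cohort` (averages mode) or list of `epoch_set`s.
#' @param condition `"error"` or `"correct"`.
#' @param min_trials minimum trials per half; subjects under it are
#'   dropped and counted.
#' @param times,channels time axis and labels when `cohort` is a list of
#'   `epoch_set`s these are taken from the sets.
#' @return List with `r`, `r_sb`, `n` (subjects used), `n_dropped`.
#' @export
eeg_split_half_reliability <- function(cohort, condition = "error",
                                       min_trials = 2L) {
  if (inherits(cohort, "cohort")) {
    times <- cohort$times
    halves <- lapply(cohort$subjects, function(s) {
      a <- s$averages
      if (is.null(a)) stop("cohort was generated without averages")
      n <- if (condition == "error") a$n_error else a$n_correct
      odd <- a[[paste0(condition, "_odd")]]
      even <- a[[paste0(condition, "_even")]]
      if (is.null(odd) || is.null(even) || floor(n / 2) < min_trials)
        return(NULL)
      rownames(odd) <- rownames(even) <- cohort$channels
      list(odd = odd, even = even)
    })
  } else {
    times <- cohort[[1]]$times
    halves <- lapply(cohort, function(es) {
      idx <- which(es$trials$condition == condition)
      odd <- idx[seq_along(idx) %% 2 == 1L]
      even <- idx[seq_along(idx) %% 2 == 0L]
      if (length(odd) < min_trials || length(even) < min_trials) return(NULL)
      list(odd = rowMeans(es$data[, , odd, drop = FALSE], dims = 2L),
           even = rowMeans(es$data[, , even, drop = FALSE], dims = 2L))
    })
  }
  n_dropped <- sum(vapply(halves, is.null, logical(1)))
  halves <- halves[!vapply(halves, is.null, logical(1))]
  score <- function(m) {
    m <- baseline_correct(m, times = times)
    detect_ern_peak(m, times)$amplitude
  }
  amp_odd <- vapply(halves, function(h) score(h$odd), numeric(1))
  amp_even <- vapply(halves, function(h) score(h$even), numeric(1))
  out <- .split_half_core(amp_odd, amp_even)
  out$n_dropped <- n_dropped
  out
}

#' Per-subject baseline-corrected condition averages of a cohort
#'
#' Convenience accessor: pulls the stored condition averages out of a
#' cohort generated with `keep_epochs = FALSE`, baseline-corrects them,
#' and (for `"difference"`) subtracts correct from error averages.
#'
#' @param cohort a `cohort`.
#' @param condition `"error"`, `"correct"` or `"difference"`.
#' @return Named list of channels x time matrices (names = subject ids).
#' @export
cohort_condition_averages <- function(cohort, condition = "error") {
  stopifnot(inherits(cohort, "cohort"))
  lapply_named <- function(f) {
    out <- lapply(cohort$subjects, f)
    names(out) <- vapply(cohort$subjects, `[[`, numeric(1), "subject_id")
    out
  }
  grab <- function(s, what) {
    a <- s$averages
    if (is.null(a) || is.null(a[[what]]))
      stop("cohort lacks stored '", what, "' averages")
    m <- a[[what]]
    rownames(m) <- cohort$channels
    baseline_correct(m, times = cohort$times)
  }
  if (condition == "difference") {
    lapply_named(function(s) grab(s, "error") - grab(s, "correct"))
  } else {
    lapply_named(function(s) grab(s, condition))
  }
}
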