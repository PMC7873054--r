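#' Adaptive response-deadline update rule
#'
#' One step of the deadline controller: if the observed negative-feedback
#' rate exceeds 20% the deadline is relaxed by 30 ms, below 20% it is
#' tightened by 30 ms, at exactly 20% it is left unchanged. The deadline
#' starts at 500 ms; driven by this rule it settles where errors plus
#' deadline misses produce 20% negative feedback.
#'
#' @param current_deadline current deadline(s) in ms.
#' @param observed_negative_rate negative-feedback rate(s) in `[0, 1]`.
#' @return Updated deadline(s) in ms.
#' @examples
#' update_deadline(500, 0.25)  # 530
#' update_deadline(500, 0.20)  # 500
#' update_deadline(530, 0.10)  # 500
#' @export
update_deadline <- function(current_deadline, observed_negative_rate) {
  if (any(observed_negative_rate < 0 | observed_negative_rate > 1))
    stop("rate must lie in [0, 1]")
  current_deadline + 30 * sign(observed_negative_rate - 0.2)
}

# Trial-position indicators shared by the categorization helpers.
.trial_flags <- function(table) {
  correct <- table$correct
  n <- length(correct)
  prev_err <- c(FALSE, !correct[-n])
  prev_cor <- c(FALSE, correct[-n])
  next_err <- c(!correct[-1], FALSE)
  list(correct = correct, prev_err = prev_err, prev_cor = prev_cor,
       next_err = next_err, n = n)
}

#' Categorize trials around errors
#'
#' Splits an ordered trial stream into error trials, post-error trials
#' (correct trials immediately following an error), post-correct trials
#' (correct following correct), and pre-error trials (correct
#' immediately preceding an error). The first trial carries no post-*
#' label and the last no pre-error label; a correct trial may be both
#' pre-error and post-correct.
#'
#' @param table a behavior table with ordered rows and columns `correct`,
#'   `rt`.
#' @return A list of class `"trial_categories"`: `index` (list of row
#'   indices per category) and `summary` (data frame of counts and mean
#'   RTs).
#' @export
categorize_trials <- function(table) {
  f <- .trial_flags(table)
  idx <- list(
    error = which(!f$correct),
    post_error = which(f$correct & f$prev_err & seq_len(f$n) > 1L),
    post_correct = which(f$correct & f$prev_cor & seq_len(f$n) > 1L),
    pre_error = which(f$correct & f$next_err & seq_len(f$n) < f$n))
  summary <- data.frame(
    category = names(idx),
    n = vapply(idx, length, integer(1)),
    mean_rt = vapply(idx, function(i)
      if (length(i)) mean(table$rt[i]) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(index = idx, summary = summary)
  class(out) <- "trial_categories"
  out
}

#' @export
print.trial_categories <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Post-error slowing on incongruent trials
#'
#' The RT difference between post-error and post-correct incongruent
#' correct trials. Not computable when either set is empty (e.g. an
#' error-free stream); the result then carries `computable = FALSE`.
#'
#' @param table a behavior table with columns `congruency`, `correct`,
#'   `rt`.
#' @return List: `pes_ms`, `n_post_error`, `n_post_correct`,
#'   `computable`.
#' @export
post_error_slowing <- function(table) {
  f <- .trial_flags(table)
  incong <- table$congruency == "incongruent"
  pe <- which(f$correct & f$prev_err & incong & seq_len(f$n) > 1L)
  pc <- which(f$correct & f$prev_cor & incong & seq_len(f$n) > 1L)
  computable <- length(pe) > 0L && length(pc) > 0L
  list(pes_ms = if (computable) mean(table$rt[pe]) - mean(table$rt[pc])
       else NA_real_,
       n_post_error = length(pe), n_post_correct = length(pc),
       computable = computable)
}

#' Flanker interference effect
#'
#' RT difference between incongruent and congruent correct trials.
#'
#' @param table a behavior table.
#' @return Interference in ms (`NA` if either condition has no correct
#'   trials).
#' @export
interference_effect <- function(table) {
  ic <- table$correct & table$congruency == "incongruent"
  cc <- table$correct & table$congruency == "congruent"
  if (!any(ic) || !any(cc)) return(NA_real_)
  mean(table$rt[ic]) - mean(table$rt[cc])
}

#' Accuracy summaries of a flanker stream
#'
#' @param table a behavior table.
#' @return List: `error_rate` (fraction incorrect), `post_error_accuracy`
#'   (accuracy of trials following an error), `post_correct_accuracy`.
#' @export
accuracy_summaries <- function(table) {
  f <- .trial_flags(table)
  after_err <- f$prev_err & seq_len(f$n) > 1L
  after_cor <- f$prev_cor & seq_len(f$n) > 1L
  list(error_rate = mean(!f$correct),
       post_error_accuracy = if (any(after_err))
         mean(f$correct[after_err]) else NA_real_,
       post_correct_accuracy = if (any(after_cor))
         mean(f$correct[after_cor]) else NA_real_)
}

#' Long-run negative-feedback rate of the deadline controller
#'
#' Simulates a stationary flanker stream and reports the empirical
#' negative-feedback percentage, overall and per incentive context. With
#' the controller of [update_deadline()] this converges to 20%.
#'
#' @param n_trials_per_context trials to simulate in each context.
#' @param config a [cohort_config()] supplying the RT model.
#' @param seed integer seed.
#' @return List: `overall_pct`, `by_context` (named percentages), `n`.
#' @export
negative_feedback_rate <- function(n_trials_per_context = 1e5,
                                   config = cohort_config(),
                                   seed = 1L) {
  set.seed(seed)
  beh <- simulate_flanker_stream(
    config, list(n_trials = 2L * n_trials_per_context))
  neg <- beh$feedback == "negative"
  list(overall_pct = 100 * mean(neg),
       by_context = vapply(split(neg, beh$context), function(v)
         100 * mean(v), numeric(1)),
       n = nrow(beh))
}
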