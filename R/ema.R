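#' Score self-control failures from an EMA log
#'
#' A self-control failure (SCF) is the enactment of a conflict-laden
#' desire: an answered prompt where a desire was reported, flagged as
#' conflicting with personal goals, and nevertheless enacted. The SCF
#' rate divides the count by the number of answered prompts.
#'
#' @param log data frame for one subject with columns `prompt_index`,
#'   `answered`, `desire`, `conflict`, `resistance`, `enactment` (the
#'   schema written by [generate_cohort()]); flags on unanswered prompts
#'   may be `NA`.
#' @return A list of class `"scf_summary"`: `n_answered`, `n_desire`,
#'   `n_conflict`, `n_resist`, `n_enact`, `scf_count`, `scf_rate`.
#' @section Errors: a subject with no answered prompt has no exposure;
#'   this is signalled as an error of class `"ernscf_no_exposure"` so
#'   that cohort-level callers can exclude the subject.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2, seed = 1),
#'                           components = "ema")
#' score_scf(cohort$subjects[[1]]$ema)
#' @export
score_scf <- function(log) {
  .validate_ema_log(log)
  ans <- !is.na(log$answered) & log$answered
  n_answered <- sum(ans)
  if (n_answered == 0L) {
    stop(structure(class = c("ernscf_no_exposure", "error", "condition"),
                   list(message = "subject answered no prompts (no exposure)",
                        call = sys.call(-1))))
  }
  d <- ans & !is.na(log$desire) & log$desire
  co <- d & !is.na(log$conflict) & log$conflict
  re <- co & !is.na(log$resistance) & log$resistance
  en <- ans & !is.na(log$enactment) & log$enactment
  scf <- sum(co & en)
  out <- list(n_answered = n_answered, n_desire = sum(d),
              n_conflict = sum(co), n_resist = sum(re),
              n_enact = sum(en & d), scf_count = scf,
              scf_rate = scf / n_answered)
  class(out) <- "scf_summary"
  out
}

.validate_ema_log <- function(log) {
  need <- c("prompt_index", "answered", "desire", "conflict", "enactment")
  if (!all(need %in% names(log)))
    stop("EMA log is missing columns: ",
         paste(setdiff(need, names(log)), collapse = ", "))
  if (anyDuplicated(log$prompt_index))
    stop("duplicate prompt_index in EMA log")
  confl <- !is.na(log$conflict) & log$conflict
  des <- !is.na(log$desire) & log$desire
  if (any(confl & !des))
    stop("invalid EMA log: conflict reported without desire")
  invisible(log)
}

#' @export
print.scf_summary <- function(x, ...) {
  cat(sprintf(
    "EMA summary: %d answered, %d desires, %d conflicts, %d SCFs (rate %.3f)\n",
    x$n_answered, x$n_desire, x$n_conflict, x$scf_count, x$scf_rate))
  invisible(x)
}

#' Score every subject of a cohort
#'
#' Applies [score_scf()] per subject; subjects without exposure (no
#' answered prompts) are dropped with a message.
#'
#' @param cohort a `cohort` from [generate_cohort()] (or a list of EMA
#'   logs).
#' @return Data frame with one row per retained subject: `subject_id`,
#'   `n_answered`, `n_desire`, `n_conflict`, `n_resist`, `n_enact`,
#'   `scf_count`, `scf_rate`.
#' @export
score_ema_cohort <- function(cohort) {
  logs <- if (inherits(cohort, "cohort"))
    lapply(cohort$subjects, `[[`, "ema") else cohort
  rows <- lapply(seq_along(logs), function(i) {
    s <- tryCatch(score_scf(logs[[i]]), ernscf_no_exposure = function(e) NULL)
    if (is.null(s)) return(NULL)
    id <- if (!is.null(logs[[i]]$subject_id)) logs[[i]]$subject_id[1] else i
    data.frame(subject_id = id, n_answered = s$n_answered,
               n_desire = s$n_desire, n_conflict = s$n_conflict,
               n_resist = s$n_resist, n_enact = s$n_enact,
               scf_count = s$scf_count, scf_rate = s$scf_rate)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " subject(s) dropped for zero answered prompts")
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' EMA response rate as a percentage
#'
#' @param n_answered mean (or total) answered prompts.
#' @param n_prompts prompts issued.
#' @return `100 * n_answered / n_prompts`.
#' @examples
#' ema_response_rate(48.52, 56)  # 86.64
#' @export
ema_response_rate <- function(n_answered, n_prompts) {
  if (n_prompts <= 0) stop("n_prompts must be positive")
  100 * n_answered / n_prompts
}

#' Spearman-Brown correction of a split-half correlation
#'
#' @param r correlation between two test halves.
#' @return The corrected full-length reliability `2 r / (1 + r)`.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

# Correlate two vectors of per-subject half scores and apply the
# Spearman-Brown correction. Shared by the EMA and EEG reliabilities.
.split_half_core <- function(half1, half2) {
  ok <- is.finite(half1) & is.finite(half2)
  half1 <- half1[ok]; half2 <- half2[ok]
  if (length(half1) < 3L) stop("need at least 3 subjects with both halves")
  if (sd(half1) == 0 || sd(half2) == 0)
    stop("zero-variance half: split-half correlation undefined")
  r <- cor(half1, half2)
  list(r = r, r_sb = spearman_brown(r), n = length(half1))
}

#' Odd-even split-half reliability of the SCF rate
#'
#' Splits each subject's prompts by the parity of `prompt_index`
#' (1-based), scores each half as an SCF rate (count over answered
#' prompts within the half), correlates the half scores across subjects
#' (Pearson), and applies the Spearman-Brown correction.
#'
#' @param cohort a `cohort` or list of EMA logs.
#' @return List with `r` (raw half correlation), `r_sb` (corrected), `n`
#'   (subjects retained; subjects with no answered prompt in either half
#'   are dropped).
#' @export
ema_split_half_reliability <- function(cohort) {
  logs <- if (inherits(cohort, "cohort"))
    lapply(cohort$subjects, `[[`, "ema") else cohort
  half_rate <- function(log, parity) {
    sub <- log[log$prompt_index %% 2L == parity, , drop = FALSE]
    s <- tryCatch(score_scf(sub), ernscf_no_exposure = function(e) NULL)
    if (is.null(s)) NA_real_ else s$scf_rate
  }
  odd <- vapply(logs, half_rate, numeric(1), parity = 1L)
  even <- vapply(logs, half_rate, numeric(1), parity = 0L)
  .split_half_core(odd, even)
}
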