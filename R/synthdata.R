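#' The 23-electrode centro-parietal analysis cluster
#'
#' Ordered labels of the frontocentral/centroparietal electrode cluster
#' used for the electrode-by-time feature matrix.
#'
#' @return Character vector of 23 channel labels.
#' @export
flanker_cluster_channels <- function() {
  c("Cz", "FCz", "FC2", "CP2", "CPz", "CP1", "FC1", "Fz", "F2", "FC4",
    "C4", "CP4", "P2", "Pz", "P1", "CP3", "C3", "FC3", "F1", "PO4",
    "PO2", "PO1", "PO3")
}

#' Default scalp topography of the error-monitoring component
#'
#' Relative spatial weights of the simulated response-locked component,
#' peaking at FCz and falling off toward parieto-occipital sites, as the
#' ERN does. Channels not listed receive weight 0.
#'
#' @param channels channel labels to return weights for.
#' @return Named numeric vector of weights in `[0, 1]`, maximal at FCz.
#' @export
default_spatial_weights <- function(channels = flanker_cluster_channels()) {
  w <- c(FCz = 1, Fz = 0.92, Cz = 0.85, F1 = 0.82, F2 = 0.82,
         FC1 = 0.78, FC2 = 0.78, FC3 = 0.6, FC4 = 0.6, CPz = 0.6,
         C3 = 0.45, C4 = 0.45, CP1 = 0.45, CP2 = 0.45,
         CP3 = 0.3, CP4 = 0.3, Pz = 0.35, P1 = 0.25, P2 = 0.25,
         PO1 = 0.12, PO2 = 0.12, PO3 = 0.1, PO4 = 0.1)
  out <- ifelse(channels %in% names(w), w[channels], 0)
  names(out) <- channels
  out
}

#' Cohort generator configuration
#'
#' Bundles and validates every parameter of the synthetic cohort: EEG
#' component shape and noise, flanker reaction-time structure, EMA
#' response behavior, and the generative count model that links the
#' subject-level error-monitoring amplitude to self-control failures
#' (SCFs). The defaults reproduce the study conditions the pipeline is
#' designed for: 131 subjects, up to 56 EMA prompts with ~87% response
#' rate, 640 flanker trials, 500 Hz sampling, and the 23-electrode
#' analysis cluster.
#'
#' The SCF count of a subject with component amplitude \eqn{A_s} is drawn
#' from a negative binomial with mean
#' \eqn{\exp(b_0 + b_1 z(A_s)) \cdot \mathrm{answered}/n_{prompts}},
#' where \eqn{z} standardizes by the population mean and SD. Amplitudes
#' are signed (more negative = larger ERN), so a positive `b1` makes
#' less-negative amplitudes (weaker error monitoring) produce more SCFs.
#'
#' @param n_subjects number of subjects.
#' @param n_prompts EMA prompts issued per subject.
#' @param n_trials flanker trials per subject.
#' @param sampling_rate EEG sampling rate in Hz.
#' @param channels ordered channel labels; must contain the 23-electrode
#'   cluster of [flanker_cluster_channels()].
#' @param ern_mu,ern_sigma mean and SD (µV) of the subject-level component
#'   amplitude; the mean is negative (a negativity).
#' @param ern_latency_ms,ern_width_ms center and Gaussian SD (ms) of the
#'   component kernel.
#' @param crn_ratio fraction of the error amplitude present on correct
#'   trials (the correct-related negativity), in `[0, 1]`.
#' @param noise_sd per-sample epoch noise SD in µV (white plus 1/f).
#' @param jitter_sd_ms SD of the trial-level latency jitter of the
#'   component, in ms.
#' @param b0,b1 generative Poisson-link coefficients of the SCF model.
#' @param nb_dispersion negative-binomial size parameter (NB2 variance
#'   \eqn{\mu + \mu^2/\theta}); must be positive.
#' @param p_answer,p_desire,p_conflict_given_desire,p_resist_given_conflict
#'   probabilities of answering a prompt, reporting a desire, the desire
#'   being conflict-laden, and resisting a conflict-laden desire.
#' @param p_enact_nonconflict enactment probability for desires without
#'   conflict (cosmetic; such enactments are not SCFs).
#' @param spatial_weights named weights of the component per channel;
#'   defaults to [default_spatial_weights()].
#' @param epoch_window epoch limits in ms relative to the response.
#' @param epoch_trials which trials receive EEG epochs: the incongruent
#'   trials the analysis uses (default) or all trials.
#' @param rt list of reaction-time parameters (ms): shifted log-normal
#'   `shift`, means/SDs for congruent correct, incongruent correct and
#'   error trials, a between-subject shift SD `subject_sd`, the post-error
#'   slowing increment `post_error_ms`, and error probabilities per
#'   congruency.
#' @param desire_strength_mean,desire_strength_sd,conflict_strength_mean,conflict_strength_sd
#'   moments of the clipped-normal strength ratings (0-6 scale).
#' @param seed integer seed; the whole cohort is deterministic given the
#'   config.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 131L, n_prompts = 56L,
                          n_trials = 640L, sampling_rate = 500,
                          channels = flanker_cluster_channels(),
                          ern_mu = -8, ern_sigma = 3,
                          ern_latency_ms = 50, ern_width_ms = 20,
                          crn_ratio = 0.3, noise_sd = 20,
                          jitter_sd_ms = 10,
                          b0 = 2.1, b1 = 0.5, nb_dispersion = 2,
                          p_answer = 0.8664, p_desire = 0.7019,
                          p_conflict_given_desire = 0.3822,
                          p_resist_given_conflict = 0.69,
                          p_enact_nonconflict = 0.85,
                          spatial_weights = NULL,
                          epoch_window = c(-500, 1000),
                          epoch_trials = c("incongruent", "all"),
                          rt = list(),
                          desire_strength_mean = 2.72,
                          desire_strength_sd = 1.05,
                          conflict_strength_mean = 0.91,
                          conflict_strength_sd = 0.61,
                          seed = 1L) {
  rt_default <- list(shift = 150, congruent_mean = 290.33,
                     congruent_sd = 32.60, incongruent_mean = 380.20,
                     incongruent_sd = 32.95, error_mean = 259.52,
                     error_sd = 29.43, subject_sd = 20,
                     post_error_ms = 6.55,
                     p_error_incongruent = 0.30, p_error_congruent = 0.035)
  rt <- utils::modifyList(rt_default, rt)
  if (is.null(spatial_weights)) spatial_weights <- default_spatial_weights(channels)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_prompts = as.integer(n_prompts),
              n_trials = as.integer(n_trials),
              sampling_rate = sampling_rate, channels = channels,
              ern_mu = ern_mu, ern_sigma = ern_sigma,
              ern_latency_ms = ern_latency_ms, ern_width_ms = ern_width_ms,
              crn_ratio = crn_ratio, noise_sd = noise_sd,
              jitter_sd_ms = jitter_sd_ms, b0 = b0, b1 = b1,
              nb_dispersion = nb_dispersion, p_answer = p_answer,
              p_desire = p_desire,
              p_conflict_given_desire = p_conflict_given_desire,
              p_resist_given_conflict = p_resist_given_conflict,
              p_enact_nonconflict = p_enact_nonconflict,
              spatial_weights = spatial_weights,
              epoch_window = epoch_window,
              epoch_trials = match.arg(epoch_trials),
              rt = rt,
              desire_strength_mean = desire_strength_mean,
              desire_strength_sd = desire_strength_sd,
              conflict_strength_mean = conflict_strength_mean,
              conflict_strength_sd = conflict_strength_sd,
              seed = as.integer(seed))
  .validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

.validate_cohort_config <- function(cfg) {
  probs <- c(cfg$p_answer, cfg$p_desire, cfg$p_conflict_given_desire,
             cfg$p_resist_given_conflict, cfg$p_enact_nonconflict,
             cfg$crn_ratio, cfg$rt$p_error_incongruent,
             cfg$rt$p_error_congruent)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (cfg$ern_sigma <= 0 || cfg$noise_sd < 0 || cfg$nb_dispersion <= 0)
    stop("configuration error: ern_sigma and nb_dispersion must be positive, noise_sd nonnegative")
  if (anyDuplicated(cfg$channels))
    stop("configuration error: duplicate channel labels")
  missing <- setdiff(flanker_cluster_channels(), cfg$channels)
  if (length(missing))
    stop("configuration error: channels must include the analysis cluster; missing ",
         paste(missing, collapse = ", "))
  if (cfg$n_subjects < 1 || cfg$n_prompts < 1 || cfg$n_trials < 1)
    stop("configuration error: counts must be positive")
  if (is.null(names(cfg$spatial_weights)) ||
      !all(names(cfg$spatial_weights) %in% cfg$channels))
    stop("configuration error: spatial_weights must be named by channels")
  invisible(cfg)
}

# Shifted log-normal parameters hitting a target mean/sd above `shift`.
.lognorm_params <- function(mean, sd, shift) {
  m <- mean - shift
  if (m <= 0) stop("RT mean must exceed the log-normal shift")
  s2 <- log(1 + (sd / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a flanker trial stream with an adaptive response deadline
#'
#' Generates per-trial congruency, incentive context, reaction time,
#' accuracy, the response deadline in force, and feedback. Error trials
#' draw from a faster RT component than correct trials; trials following
#' an error are slowed by `rt$post_error_ms`. Feedback is negative when
#' the response is wrong or slower than the context's deadline, which the
#' controller of [update_deadline()] adapts (±30 ms around an initial
#' 500 ms) toward a 20% negative-feedback rate. The deadline is stepped
#' once per completed block of 50 trials of a context, from that block's
#' negative-feedback rate; blockwise stepping keeps the controller stable
#' so the deadline settles near the RT distribution's 80th percentile.
#'
#' @param config a [cohort_config()] (only `n_trials` and `rt` are used
#'   unless overridden).
#' @param subject_state optional list: `rt_shift` (ms added to every RT of
#'   this subject), `n_trials` (override the config).
#' @return A `BehaviorTable` data frame: `trial`, `congruency`, `context`,
#'   `rt`, `correct`, `deadline`, `feedback`.
#' @export
simulate_flanker_stream <- function(config = cohort_config(),
                                    subject_state = list()) {
  rt <- config$rt
  n <- if (!is.null(subject_state$n_trials)) as.integer(subject_state$n_trials)
       else config$n_trials
  shift <- if (!is.null(subject_state$rt_shift)) subject_state$rt_shift else 0

  congruency <- sample(c("congruent", "incongruent"), n, replace = TRUE)
  context <- sample(c("gain", "loss"), n, replace = TRUE)
  p_err <- ifelse(congruency == "incongruent",
                  rt$p_error_incongruent, rt$p_error_congruent)
  correct <- runif(n) >= p_err

  pc <- .lognorm_params(rt$congruent_mean, rt$congruent_sd, rt$shift)
  pinc <- .lognorm_params(rt$incongruent_mean, rt$incongruent_sd, rt$shift)
  pe <- .lognorm_params(rt$error_mean, rt$error_sd, rt$shift)
  ml <- ifelse(correct,
               ifelse(congruency == "incongruent", pinc["meanlog"], pc["meanlog"]),
               pe["meanlog"])
  sl <- ifelse(correct,
               ifelse(congruency == "incongruent", pinc["sdlog"], pc["sdlog"]),
               pe["sdlog"])
  rts <- rt$shift + exp(rnorm(n, ml, sl)) + shift
  post_err <- c(FALSE, !correct[-n])
  rts <- rts + rt$post_error_ms * post_err

  # blockwise controller: every `win_len` trials of a context the deadline
  # is stepped once, from the negative-feedback rate of that fresh block
  # (a per-trial step on a lagging running rate is marginally stable and
  # produces large deadline limit cycles)
  win_len <- 50L
  deadline <- numeric(n)
  feedback <- character(n)
  dl <- c(gain = 500, loss = 500)
  nneg <- c(gain = 0L, loss = 0L)
  ntr <- c(gain = 0L, loss = 0L)
  for (i in seq_len(n)) {
    ctx <- context[i]
    deadline[i] <- dl[[ctx]]
    neg <- !correct[i] || rts[i] > dl[[ctx]]
    feedback[i] <- if (neg) "negative"
      else if (ctx == "gain") "positive" else "neutral"
    nneg[[ctx]] <- nneg[[ctx]] + neg
    ntr[[ctx]] <- ntr[[ctx]] + 1L
    if (ntr[[ctx]] == win_len) {
      dl[[ctx]] <- update_deadline(dl[[ctx]], nneg[[ctx]] / win_len)
      nneg[[ctx]] <- 0L
      ntr[[ctx]] <- 0L
    }
  }
  data.frame(trial = seq_len(n), congruency = congruency, context = context,
             rt = rts, correct = correct, deadline = deadline,
             feedback = feedback, stringsAsFactors = FALSE)
}

# White + 1/f ("pink") noise, equal power split, unit variance per sample.
# Returns an ntime x ncol matrix; columns are independent realizations.
.shaped_noise <- function(ntime, ncol, sampling_rate, nfft = 1024L) {
  stopifnot(ntime <= nfft)
  k <- seq_len(nfft) - 1L
  f <- pmin(k, nfft - k) * sampling_rate / nfft  # two-sided frequency axis
  f[f == 0] <- sampling_rate / nfft
  h <- sqrt(0.5 + 0.5 / (f / f[2L]))  # amplitude filter: white + 1/f power
  h <- h / sqrt(mean(h^2))
  out <- matrix(0, ntime, ncol)
  block <- max(1L, floor(4e6 / nfft))
  done <- 0L
  while (done < ncol) {
    nb <- min(block, ncol - done)
    e <- matrix(rnorm(nfft * nb), nfft, nb)
    x <- Re(mvfft(mvfft(e) * h, inverse = TRUE)) / nfft
    out[, (done + 1L):(done + nb)] <- x[seq_len(ntime), , drop = FALSE]
    done <- done + nb
  }
  out
}

# Gaussian component kernel evaluated on `times`, centered at
# latency + jitter (all ms). Returns ntime x length(jitter) matrix.
.component_kernel <- function(times, latency, width, jitter) {
  outer(times, latency + jitter, function(t, c) exp(-(t - c)^2 / (2 * width^2)))
}

# Epochs for one subject. Returns list(data = ch x time x trial array,
# times, channels, trials = trial table).
.subject_epochs <- function(config, beh, amplitude) {
  step <- 1000 / config$sampling_rate
  times <- seq(config$epoch_window[1], config$epoch_window[2], by = step)
  use <- if (config$epoch_trials == "incongruent")
    which(beh$congruency == "incongruent") else seq_len(nrow(beh))
  ntr <- length(use)
  nch <- length(config$channels)
  ntime <- length(times)

  condition <- ifelse(beh$congruency[use] == "incongruent",
                      ifelse(beh$correct[use], "correct", "error"),
                      "congruent")
  amp <- ifelse(condition == "error", amplitude, config$crn_ratio * amplitude)
  jit <- rnorm(ntr, 0, config$jitter_sd_ms)
  S <- .component_kernel(times, config$ern_latency_ms, config$ern_width_ms,
                         jit)  # ntime x ntr
  S <- S * matrix(amp, ntime, ntr, byrow = TRUE)

  if (config$noise_sd > 0) {
    noise <- .shaped_noise(ntime, nch * ntr, config$sampling_rate) *
      config$noise_sd
    x <- array(noise, dim = c(ntime, nch, ntr))
  } else {
    x <- array(0, dim = c(ntime, nch, ntr))
  }
  w <- config$spatial_weights[config$channels]
  w[is.na(w)] <- 0
  for (ch in seq_len(nch)) {
    if (w[ch] != 0) x[, ch, ] <- x[, ch, ] + w[ch] * S
  }
  trials <- data.frame(trial = beh$trial[use], condition = condition,
                       congruency = beh$congruency[use],
                       accuracy = beh$correct[use],
                       context = beh$context[use], rt = beh$rt[use],
                       stringsAsFactors = FALSE)
  # data kept time x ch x trial; callers permute if they need ch-major
  list(data = x, times = times, channels = config$channels, trials = trials)
}

# Condition averages (full and odd/even halves) for one subject without
# materializing a permuted epoch array. `x` is time x ch x trial.
.condition_means <- function(x, idx) {
  if (length(idx) == 0L) return(NULL)
  t(rowMeans(x[, , idx, drop = FALSE], dims = 2L))
}

# Condition averages for one subject drawn directly at the average level.
# The mean of m independent Gaussian noise epochs has the same spectral
# shape with SD/sqrt(m), so the odd/even half-averages can be sampled
# exactly without materializing single trials; the full average is the
# trial-count-weighted combination of the halves. Trial-level latency
# jitter is still drawn per trial and enters through the averaged kernel.
.subject_average_stats <- function(config, beh, amplitude, times) {
  use <- if (config$epoch_trials == "incongruent")
    which(beh$congruency == "incongruent") else seq_len(nrow(beh))
  condition <- ifelse(beh$congruency[use] == "incongruent",
                      ifelse(beh$correct[use], "correct", "error"),
                      "congruent")
  jit <- rnorm(length(use), 0, config$jitter_sd_ms)
  w <- config$spatial_weights[config$channels]
  w[is.na(w)] <- 0
  nch <- length(config$channels)
  ntime <- length(times)

  half_avg <- function(idx, amp) {
    if (length(idx) == 0L) return(NULL)
    g <- rowMeans(.component_kernel(times, config$ern_latency_ms,
                                    config$ern_width_ms, jit[idx]))
    sig <- outer(w, amp * g)  # ch x time
    if (config$noise_sd > 0) {
      noise <- t(.shaped_noise(ntime, nch, config$sampling_rate)) *
        (config$noise_sd / sqrt(length(idx)))
      sig <- sig + noise
    }
    sig
  }
  combine <- function(h1, n1, h2, n2) {
    if (is.null(h1) && is.null(h2)) return(NULL)
    if (is.null(h2)) return(h1)
    if (is.null(h1)) return(h2)
    (n1 * h1 + n2 * h2) / (n1 + n2)
  }
  out <- list()
  for (cond in c("error", "correct")) {
    idx <- which(condition == cond)
    odd <- idx[seq_along(idx) %% 2 == 1L]
    even <- idx[seq_along(idx) %% 2 == 0L]
    amp <- if (cond == "error") amplitude else config$crn_ratio * amplitude
    ho <- half_avg(odd, amp)
    he <- half_avg(even, amp)
    out[[paste0(cond, "_odd")]] <- ho
    out[[paste0(cond, "_even")]] <- he
    out[[cond]] <- combine(ho, length(odd), he, length(even))
    out[[paste0("n_", cond)]] <- length(idx)
  }
  out
}

# EMA log for one subject; SCF count drawn from the generative NB model.
.subject_ema <- function(config, subject_id, z_amp) {
  np <- config$n_prompts
  answered <- rbinom(np, 1L, config$p_answer) == 1L
  desire <- conflict <- resistance <- enactment <- rep(NA, np)
  desire_strength <- conflict_strength <- rep(NA_real_, np)
  na <- sum(answered)
  desire[answered] <- rbinom(na, 1L, config$p_desire) == 1L
  d_idx <- which(answered & desire)
  conflict[answered] <- FALSE
  conflict[d_idx] <- rbinom(length(d_idx), 1L,
                            config$p_conflict_given_desire) == 1L
  c_idx <- which(answered & desire & conflict)
  resistance[d_idx] <- FALSE
  resistance[c_idx] <- rbinom(length(c_idx), 1L,
                              config$p_resist_given_conflict) == 1L
  desire_strength[d_idx] <- pmin(6, pmax(0, rnorm(length(d_idx),
      config$desire_strength_mean, config$desire_strength_sd)))
  conflict_strength[c_idx] <- pmin(6, pmax(0, rnorm(length(c_idx),
      config$conflict_strength_mean, config$conflict_strength_sd)))

  exposure <- na / np
  mu <- exp(config$b0 + config$b1 * z_amp) * exposure
  scf <- rnbinom(1L, size = config$nb_dispersion, mu = mu)
  # an SCF presupposes a conflict-laden desire: when the drawn count
  # exceeds the conflicts reported so far, promote further answered
  # prompts to conflict-laden desires (failure-prone periods carry more
  # conflicts); the count itself is only capped by the answered prompts
  if (scf > length(c_idx)) {
    pool <- setdiff(which(answered), c_idx)
    need <- min(scf, sum(answered)) - length(c_idx)
    if (need > 0) {
      add <- if (length(pool) > need) sample(pool, need) else pool
      desire[add] <- TRUE
      conflict[add] <- TRUE
      resistance[add] <- rbinom(length(add), 1L,
                                config$p_resist_given_conflict) == 1L
      desire_strength[add] <- pmin(6, pmax(0, rnorm(length(add),
          config$desire_strength_mean, config$desire_strength_sd)))
      conflict_strength[add] <- pmin(6, pmax(0, rnorm(length(add),
          config$conflict_strength_mean, config$conflict_strength_sd)))
      d_idx <- which(answered & desire)
      c_idx <- which(answered & desire & conflict)
    }
    scf <- min(scf, length(c_idx))
  }
  enact_idx <- if (scf > 0) sample(c_idx, scf) else integer(0)
  enactment[d_idx] <- FALSE
  enactment[setdiff(d_idx, c_idx)] <-
    rbinom(length(setdiff(d_idx, c_idx)), 1L, config$p_enact_nonconflict) == 1L
  enactment[enact_idx] <- TRUE

  scf <- as.integer(scf)
  log <- data.frame(subject_id = subject_id, prompt_index = seq_len(np),
                    answered = answered, desire = desire,
                    desire_strength = desire_strength, conflict = conflict,
                    conflict_strength = conflict_strength,
                    resistance = resistance, enactment = enactment,
                    stringsAsFactors = FALSE)
  list(log = log, scf_count = scf, n_answered = na,
       expected_scf_mean = mu)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort of subjects, each with (a) a subject-level component
#' amplitude \eqn{A_s \sim N(\mu, \sigma^2)}, (b) a flanker behavior
#' stream from [simulate_flanker_stream()], (c) response-locked EEG
#' epochs in which error trials carry the negative frontocentral
#' component \eqn{A_s\, w_{ch}\, g(t)} (correct trials a `crn_ratio`
#' fraction of it) on top of white-plus-1/f noise, and (d) an EMA log
#' whose SCF count is negative-binomial with mean
#' \eqn{\exp(b_0 + b_1 z(A_s))} times the answered-prompt exposure.
#' Identical configs (including `seed`) give bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param components which data streams to generate; dropping `"eeg"`
#'   makes large EMA/behavior-only cohorts cheap.
#' @param keep_epochs if `TRUE`, full per-subject `epoch_set` objects are
#'   generated trial by trial (memory-heavy; use small cohorts). The
#'   default keeps only per-subject condition averages (full and odd/even
#'   trial halves), drawn directly from the exact sampling distribution
#'   of the average (Gaussian noise averages are Gaussian with SD scaled
#'   by the root trial count), which is distributionally identical and
#'   much cheaper. With `noise_sd = 0` the two modes agree exactly.
#' @return A list of class `"cohort"`: `subjects` (per-subject list with
#'   `ema`, `behavior`, `averages` or `epochs`), `truth` (data frame with
#'   `subject_id`, `ern_amplitude`, `n_answered`, `expected_scf_mean`,
#'   `scf_count`; attributes `b0`, `b1`, `support`), `times`, `channels`,
#'   `config`. The `support` attribute lists the (channel, time) pairs
#'   carrying generative signal: channels with at least half the maximum
#'   spatial weight, times within 2 effective SDs of the kernel center
#'   (kernel width and latency jitter combined).
#' @export
generate_cohort <- function(config = cohort_config(),
                            components = c("eeg", "ema", "behavior"),
                            keep_epochs = FALSE) {
  .validate_cohort_config(config)
  components <- match.arg(components, c("eeg", "ema", "behavior"),
                          several.ok = TRUE)
  set.seed(config$seed)
  ns <- config$n_subjects
  amplitude <- rnorm(ns, config$ern_mu, config$ern_sigma)
  z_amp <- (amplitude - config$ern_mu) / config$ern_sigma
  rt_shift <- rnorm(ns, 0, config$rt$subject_sd)

  step <- 1000 / config$sampling_rate
  times <- seq(config$epoch_window[1], config$epoch_window[2], by = step)

  subjects <- vector("list", ns)
  truth <- data.frame(subject_id = seq_len(ns), ern_amplitude = amplitude,
                      n_answered = NA_integer_,
                      expected_scf_mean = NA_real_, scf_count = NA_integer_)
  for (s in seq_len(ns)) {
    subj <- list(subject_id = s)
    if ("behavior" %in% components || "eeg" %in% components) {
      beh <- simulate_flanker_stream(config,
                                     list(rt_shift = rt_shift[s]))
      if ("behavior" %in% components) subj$behavior <- beh
    }
    if ("eeg" %in% components) {
      if (keep_epochs) {
        ep <- .subject_epochs(config, beh, amplitude[s])
        subj$epochs <- epoch_set(aperm(ep$data, c(2, 1, 3)), ep$times,
                                 ep$channels, ep$trials)
      } else {
        subj$averages <- .subject_average_stats(config, beh, amplitude[s],
                                                times)
      }
    }
    if ("ema" %in% components) {
      ema <- .subject_ema(config, s, z_amp[s])
      subj$ema <- ema$log
      truth$n_answered[s] <- ema$n_answered
      truth$expected_scf_mean[s] <- ema$expected_scf_mean
      truth$scf_count[s] <- ema$scf_count
    }
    subjects[[s]] <- subj
  }

  w <- config$spatial_weights[config$channels]
  w[is.na(w)] <- 0
  sigma_eff <- sqrt(config$ern_width_ms^2 + config$jitter_sd_ms^2)
  sup_ch <- config$channels[w >= 0.5 * max(w)]
  sup_t <- times[abs(times - config$ern_latency_ms) <= 2 * sigma_eff]
  support <- expand.grid(channel = sup_ch, time_ms = sup_t,
                         stringsAsFactors = FALSE)
  attr(truth, "b0") <- config$b0
  attr(truth, "b1") <- config$b1
  attr(truth, "support") <- support

  out <- list(subjects = subjects, truth = truth, times = times,
              channels = config$channels, config = config)
  class(out) <- "cohort"
  out
}

#' Configuration of the parameter-recovery validation study
#'
#' A cohort configuration with the error-monitoring component injected at
#' a single frontal channel (Fz) and a compact 50-80 ms temporal support
#' (Gaussian kernel centered at 65 ms, SD 7.5 ms, no latency jitter, so
#' the 2-sigma support is exactly 50-80 ms), a strong amplitude-to-count
#' association (`b1 = 0.8`, dispersion 8, giving an amplitude-count
#' correlation near 0.8) and moderate epoch noise (10 µV). Used by the
#' validation suite to test whether the adaptive elastic net recovers
#' the injected (channel, time) support as its most important features.
#'
#' @param seed integer seed for the cohort.
#' @return A [cohort_config()].
#' @export
recovery_study_config <- function(seed = 1L) {
  cohort_config(seed = seed, spatial_weights = c(Fz = 1),
                ern_latency_ms = 65, ern_width_ms = 7.5,
                jitter_sd_ms = 0, b1 = 0.8, nb_dispersion = 8,
                noise_sd = 10)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d channels, seed %d\n",
              length(x$subjects), length(x$channels), x$config$seed))
  invisible(x)
}
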