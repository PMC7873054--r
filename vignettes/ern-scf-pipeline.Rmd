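---
title: "Linking error-related EEG activity to daily-life self-control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking error-related EEG activity to daily-life self-control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

The error-related negativity (ERN) is a frontocentral negative deflection of
the response-locked EEG that peaks roughly 50–100 ms after an erroneous
response, is maximal around FCz, and is commonly read as a neural index of
performance monitoring. A stable trait-like component of its amplitude makes
it a candidate predictor of *regulatory control outside the laboratory*:
people whose monitoring system responds weakly to errors may recruit less
interventive self-control in everyday temptation conflicts.

`ernscf` implements a complete, testable pipeline for this question. The
outcome is the number of **self-control failures (SCFs)** a person reports
under ecological momentary assessment (EMA): an SCF is the *enactment of a
conflict-laden desire* — an answered smartphone prompt on which the
respondent reported a desire, flagged it as conflicting with personal goals,
and enacted it anyway. The predictor is the person's response-locked EEG
activity in a flanker task, either as the full electrode-by-time pattern
(for the penalized regression) or as the individual peak amplitude (for the
confirmatory count regression).

## Pipeline overview

1. **EMA scoring** (`score_scf`, `score_ema_cohort`): per subject, count
   answered prompts, desires, conflicts, resistance, enactments; the SCF
   count and the SCF rate (count / answered prompts). A subject with no
   answered prompt has no exposure and is excluded with a typed error.
2. **ERP processing** (`baseline_correct`, `condition_average`,
   `build_feature_matrix`, `detect_ern_peak`): response-locked epochs
   (−500…1000 ms, 500 Hz) are baseline-corrected against the −400…−200 ms
   pre-response mean, averaged within subject by condition, and flattened
   into a subjects × (electrode, time) design matrix over a 23-electrode
   cluster and a −50…300 ms analysis window.
3. **Penalized regression** (`fit_poisson_enet`, `tune_poisson_enet`,
   `fit_aenet`, `bootstrap_632`, `variable_importance`): a Poisson
   adaptive elastic net predicting SCF counts from the feature matrix,
   tuned by repeated cross-validation and internally validated with the
   0.632 bootstrap.
4. **Confirmatory statistics** (`negbin_glm_scf`, `yuen_boot_dep`,
   `pointwise_error_vs_correct`): a negative-binomial GLM of SCF counts on
   peak amplitude, robust trimmed-mean contrasts for the skewed behavioral
   measures, and Bonferroni-corrected pointwise waveform tests.
5. **Synthetic cohorts** (`cohort_config`, `generate_cohort`): a generator
   with known ground truth that makes every step testable end to end.

## The penalized count model

With subject features \(x_i\) (mean amplitudes per electrode and time
point, µV) and SCF counts \(y_i\), the solver minimizes

\[
\frac{1}{n}\sum_i \left(e^{\eta_i} - y_i \eta_i\right)
 + \lambda \sum_j v_j\!\left(\alpha\,|\beta_j| +
 \tfrac{1-\alpha}{2}\,\beta_j^2\right),
\qquad \eta_i = \beta_0 + x_i^\top\beta + o_i ,
\]

by iteratively reweighted least squares with cyclic coordinate descent on
the working response, an unpenalized intercept, and internal
standardization of the features (coefficients are reported on the original
scale). \(o_i\) is an optional log-exposure offset (log of the answered
prompt fraction). The implementation is compiled (Rcpp) and uses
sequential strong-rule screening with a full KKT check, warm starts along
a decreasing \(\lambda\) path, and objective-guarded step halving, so the
penalized objective is non-increasing across outer iterations (a property
the test suite asserts).

**Adaptive stage.** The adaptive elastic net refits with per-feature
penalty factors \(v_j = (|\hat\beta_j| + 1/n)^{-\gamma}\) rescaled to mean
one, where \(\hat\beta\) comes from the tuned plain elastic net. Features
the first stage shrank to zero are penalized heavily, features with large
coefficients barely — the construction behind oracle-style selection
consistency. The exponent defaults to \(\gamma = 1\); theory for
\(p \gg n\) favors larger exponents, and the package's own recovery study
(below) uses \(\gamma = 2\).

**Tuning.** `tune_poisson_enet` evaluates an \(\alpha\) grid
(default \(\{0.1, 0.25, 0.5, 0.75, 0.9, 1.0\}\)) crossed with a per-alpha
log-spaced \(\lambda\) path by repeated k-fold cross-validation (default
5 folds × 10 repeats), scoring held-out RMSE between observed counts and
predicted means \(e^{\hat\eta}\). The minimizing cell is selected; exact
ties break toward the larger (sparser) \(\lambda\). The path spans
\(\lambda_{max}\) (the smallest penalty with an all-zero solution,
computed from the data) down to \(10^{-4}\lambda_{max}\) — except when
\(p > n\), where the default floor is \(0.01\lambda_{max}\): beyond that
the fits are nearly unpenalized interpolators that cross-validation never
selects, and the coordinate descent spends almost all of its time there.

**Validation.** `bootstrap_632` refits the model at fixed hyperparameters
on bootstrap resamples and combines apparent and out-of-bag RMSE as
\(err_{.632} = 0.368\,err_{app} + 0.632\,\overline{err}_{oob}\).
Resamples that leave no row out of bag are skipped and counted. No inner
re-tuning is performed — the estimate validates the *tuned* model, and
nested tuning at these sample sizes mostly adds variance.

**Importance.** Importance ranks the nonzero coefficients of the tuned
model by absolute value **on the standardized scale** (the scale the model
is estimated on). Original-scale coefficients divide by the feature SD, so
low-variance pure-noise features would be inflated relative to
signal-carrying features; the standardized scale makes coefficients
comparable across features. Tables report both (`estimate`,
`estimate_std`), mapped back to (electrode, time) labels.

**Outcome scale.** SCFs are defined as a *rate* but modeled as integer
*counts* under a Poisson/negative-binomial likelihood; exposure differences
between subjects enter through the optional log-exposure offset. Both
modes are supported; counts are the default.

## Confirmatory statistics

* `negbin_glm_scf` fits an NB2 log-link GLM (variance
  \(\mu + \mu^2/\theta\), \(\theta\) by maximum likelihood) of SCF counts
  on peak amplitude, with Wald \(z = \hat\beta/\widehat{SE}\) and a
  two-sided normal p value. On equidispersed data it converges to the
  Poisson GLM, which the tests assert.
* `yuen_boot_dep` compares paired samples by the difference of 20%-trimmed
  means with a standard error from winsorized variances and covariance.
  The reference distribution is a bootstrap-t over paired resamples of the
  *centered* data (B = 599 by default), giving a symmetric percentile-t CI
  and p value. The bootstrap-t variant was chosen over plain percentile
  bootstrapping for its better small-sample calibration with trimmed
  means; with `trim = 0` the statistic reduces to the ordinary paired
  t statistic, bootstrapped. A constant paired shift is recovered exactly
  in the point estimate with a degenerate (point) interval.
* `pointwise_error_vs_correct` runs paired t tests at each (electrode,
  time) of the analysis window at FCz and Fz, with Bonferroni
  \(m = 2 \times 175 = 350\) by default — the conservative joint count;
  per-electrode correction is available by flag. Contiguous significant
  time runs are reported as windows.

## The synthetic cohort generator

`generate_cohort` draws, per subject:

* a component amplitude \(A_s \sim N(\mu_{ern}, \sigma_{ern}^2)\)
  (defaults −8 ± 3 µV; signed, so *more negative = larger ERN*);
* a flanker stream with shifted log-normal RTs per condition
  (defaults match a fast error component at ≈260 ms, correct congruent
  ≈290 ms, incongruent ≈380 ms, SDs ≈30 ms), error probabilities 0.30
  (incongruent) and 0.035 (congruent) giving a ≈16.75% overall error
  rate, a configurable post-error slowing increment (default 6.55 ms),
  and the adaptive deadline controller;
* response-locked epochs for the incongruent trials in which error trials
  carry \(A_s\, w_{ch}\, g(t)\) — a Gaussian temporal kernel \(g\)
  (latency 50 ms, SD 20 ms by default, per-trial latency jitter SD 10 ms)
  weighted across channels by a topography peaking at FCz — and correct
  trials carry a `crn_ratio` (default 0.3) fraction of it, on top of
  white-plus-1/f noise (default 20 µV per sample, equal power split);
* an EMA log whose per-subject SCF count is negative-binomial with mean
  \(\exp(b_0 + b_1 z(A_s)) \times \text{answered}/56\): with \(b_1 > 0\),
  *less negative* amplitudes (weaker error monitoring) produce more
  failures. Prompt-level flags (answer 0.8664, desire 0.7019, conflict
  given desire 0.3822, resistance given conflict 0.69) reproduce
  cohort-level EMA summaries; if the drawn count exceeds the conflicts
  generated so far, additional answered prompts are promoted to
  conflict-laden desires so the count model is honored exactly.

**Deadline controller.** Feedback is negative when the response is wrong
or slower than the context's deadline. The deadline starts at 500 ms and
steps ±30 ms toward a 20% negative-feedback rate. The step is applied
once per completed 50-trial block of a context, using that block's rate: a
per-trial step driven by a lagging running-window rate was implemented
first and found marginally stable (deadline limit cycles of several
hundred ms, though the long-run rate still balanced at 20%); blockwise
stepping keeps both the 20% rate and the deadline near the RT
distribution's 80th percentile, and matches how adaptive deadlines are
operated in practice. In the gain context a response slower than the
deadline forfeits the reward, in the loss context it is punished; both
are scored "negative", which is what the controller regulates.

**Average-level sampling.** By default the generator returns per-subject
condition averages (plus odd/even trial half-averages for reliability
work) drawn directly from the exact sampling distribution of the average:
the mean of \(m\) independent Gaussian noise epochs is Gaussian noise with
the same spectral shape and SD scaled by \(1/\sqrt m\), and the averaged
kernel still uses per-trial jitter draws. `keep_epochs = TRUE` generates
genuine single trials instead; with `noise_sd = 0` the two modes agree
exactly (asserted in the tests). Average-level sampling is what makes
131-subject, 640-trial cohorts cheap enough to repeat across many seeds.

**What the generator does and does not emulate.** It reproduces the
epoch-level statistical structure the analysis assumes: component
topography, latency and jitter, error/correct amplitude asymmetry,
1/f-plus-white noise, trial-count-limited reliability (error-average
split-half reliability ≈0.95 at default settings), EMA response and flag
rates, overdispersed counts linked to amplitude, and flanker RT/accuracy
structure with post-error adaptations. It does *not* emulate artifacts,
volume-conduction correlations between channels (channel noise is
independent), non-stationarities over the session, EMA time-of-day
structure, or dependence between prompts — so passing recovery tests show
the *pipeline* behaves correctly under its assumptions, not that real data
meet them. Its EMA reliability (≈0.9) is higher than typically observed in
the field (≈0.77), because prompts are conditionally independent given the
subject's rate.

## Validation studies shipped with the package

The test suite (`tests/testthat/`) includes, besides unit oracles
(closed-form examples, brute-force grid minimization of the convex
penalized objective, an independent penalized-regression library as a
cross-check, independently coded bootstrap oracles):

* **Deadline study**: 10^5 trials per context; the negative-feedback rate
  must land within ±2 percentage points of 20%.
* **Recovery study** (`recovery_study_config`): 20 cohorts of 131
  subjects with the component injected at a single frontal channel (Fz)
  with temporal support exactly 50–80 ms (kernel 65 ± 7.5 ms, no jitter),
  10 µV noise, and a strong amplitude–count link (\(b_1 = 0.8\),
  \(\theta = 8\), amplitude–count correlation ≈ 0.75–0.8). The pipeline
  runs with \(\alpha \in \{0.75, 1\}\), 25-value \(\lambda\) paths,
  5 × 3 cross-validation and \(\gamma = 2\); a cohort passes when every
  top-4 importance feature lies in the injected (channel, time) support
  with the generative (positive) sign.
* **Null-safety study**: outcomes permuted against the features; the
  tuned pipeline should select zero features in at least 70% of runs.
* **Type-I study**: the bootstrapped Yuen test's rejection rate under a
  paired null (100 replicates, n = 40) must stay near 5%.

Problem sizes (repeats, path lengths, replicate counts) are the package's
validation-study choices and are stated in the tests themselves.

## Known limitations

* **Minimum-RMSE tuning overselects.** With \(p = 4025\) features and
  \(n = 131\) subjects the repeated-CV RMSE curve is nearly flat around
  its minimum relative to its Monte-Carlo noise, so the selected
  \(\lambda\) often sits deep enough that one or two spuriously
  correlated noise features (the extreme order statistics among ~4000
  candidates, \(|r| \approx 0.3\) at this n) survive with coefficients
  comparable to the weaker true features. The adaptive stage reduces but
  cannot eliminate them — they are genuinely correlated with the outcome
  *in this sample*. In the shipped recovery study roughly a third of
  cohorts retain such a feature within the top four, so the strict
  "all top-4 in support in ≥16/20 cohorts" check can fail even though the
  leading features are essentially always in the injected support. A
  one-standard-error selection rule or stability selection would fix
  this but would be a different tuning procedure than the one specified
  for this pipeline. The same mechanism limits *null safety*: with
  permuted outcomes all sparse-end path cells share a single CV RMSE
  value while hundreds of deeper cells differ from it only by a small
  overfitting bias plus Monte-Carlo noise, so the minimum regularly
  lands below the first feature's entry point and the "tuned" null model
  retains a handful of features. Increasing the number of CV repeats
  shrinks the noise and improves both behaviors, at a steep runtime
  cost.
* The generator's independence assumptions (channels, prompts) make the
  synthetic problem *harder* than real EEG in one respect (no
  volume-conduction grouping across neighboring channels for the elastic
  net to exploit) and easier in others (no artifacts, no drift).
* `negbin_glm_scf` relies on `MASS::glm.nb`; very underdispersed data can
  produce dispersion-profile warnings as \(\theta \to \infty\) (the
  Poisson limit), which is expected behavior.
* The Yuen bootstrap uses the bootstrap-t variant; percentile variants
  give slightly different p values, especially at small B.
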