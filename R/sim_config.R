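#' Simulation configuration for a synthetic antisaccade cohort
#'
#' Bundles every generating parameter of the synthetic cohort: group sizes,
#' trial-sequence length distribution, the logit-scale coefficients of the
#' trial-history model (per-group intercepts plus slopes per consecutive
#' preceding success/failure), the participant random-intercept SD, per-group
#' error-correction probabilities, and the rise-to-threshold reaction-time
#' parameters.
#'
#' The default coefficients are the fitted run-length model of the cohort the
#' package emulates: control intercept 0.741 with MCI/AD offsets -0.200/-0.344,
#' slopes +0.047 per consecutive previous success and -0.040 per consecutive
#' previous failure, and random-intercept SD 1.374. The linear predictor is
#' the logit of the probability of the *reference outcome*; by default the
#' reference outcome is `"correct"`, under which the default intercepts imply
#' a control error rate of about 1 - plogis(0.741) = 0.32 and previous
#' successes make a further success more likely. Set
#' `reference_outcome = "error"` to flip the response coding (the generator
#' then interprets the same linear predictor as the logit of an error).
#'
#' @param group_sizes Named integer vector, participants per group
#'   (default `c(control = 95, mci = 65, ad = 42)`).
#' @param n_trials_full Trials in a complete sequence (default 24).
#' @param p_full_sequence Probability a participant completes all trials
#'   (default 0.792).
#' @param short_len_range Inclusive integer range for incomplete sequence
#'   lengths (default 11--23).
#' @param p_short_near_full Probability an incomplete sequence falls in the
#'   top three lengths of `short_len_range` (mass concentrated just below a
#'   full sequence; default 0.9).
#' @param intercepts Named vector: control intercept and MCI/AD offsets on
#'   the logit scale (treatment coding, control reference).
#' @param slope_success Logit-scale slope per immediately preceding
#'   consecutive correct trial.
#' @param slope_error Logit-scale slope per immediately preceding consecutive
#'   error trial.
#' @param sigma_u Participant random-intercept SD (logit units, >= 0).
#' @param reference_outcome `"correct"` (default) or `"error"`: the outcome
#'   whose probability the linear predictor parameterises.
#' @param correction_prob Named vector, per-group probability that an error
#'   trial is followed by a corrective saccade.
#' @param rt_params Reaction-time model parameters, see [rt_params()].
#' @param race_mode Logical; if `TRUE` the reaction-time race (faster of the
#'   prosaccade/antisaccade units) *determines* the outcome, overriding the
#'   logistic draw. Off by default so the logit coefficients remain exactly
#'   recoverable.
#' @param seed Integer root seed used when [simulate_cohort()] is called
#'   without an explicit seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [rt_params()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$sigma_u
sim_config <- function(group_sizes = c(control = 95, mci = 65, ad = 42),
                       n_trials_full = 24,
                       p_full_sequence = 0.792,
                       short_len_range = c(11L, 23L),
                       p_short_near_full = 0.9,
                       intercepts = c(control = 0.741, mci = -0.200,
                                      ad = -0.344),
                       slope_success = 0.047,
                       slope_error = -0.040,
                       sigma_u = 1.374,
                       reference_outcome = c("correct", "error"),
                       correction_prob = c(control = 631 / 762,
                                           mci = 598 / 784,
                                           ad = 382 / 533),
                       rt_params = antiseq::rt_params(),
                       race_mode = FALSE,
                       seed = 1L) {
  reference_outcome <- match.arg(reference_outcome)
  stopifnot(
    length(group_sizes) == 3, all(group_sizes >= 1),
    n_trials_full >= 2,
    length(short_len_range) == 2,
    short_len_range[1] >= 2, short_len_range[2] < n_trials_full
  )
  if (!all(names(group_sizes) == group_levels())) {
    names(group_sizes) <- group_levels()
  }
  names(intercepts) <- group_levels()
  names(correction_prob) <- group_levels()
  probs <- c(p_full_sequence, p_short_near_full, correction_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must be finite and in [0, 1]")
  }
  coefs <- c(intercepts, slope_success, slope_error)
  if (any(!is.finite(coefs))) {
    abort("generating coefficients must be finite")
  }
  if (!is.finite(sigma_u) || sigma_u < 0) {
    abort("`sigma_u` must be finite and >= 0")
  }
  validate_rt_params(rt_params)
  structure(
    list(
      group_sizes = as.integer(group_sizes),
      n_trials_full = as.integer(n_trials_full),
      p_full_sequence = p_full_sequence,
      short_len_range = as.integer(short_len_range),
      p_short_near_full = p_short_near_full,
      intercepts = intercepts,
      slope_success = slope_success,
      slope_error = slope_error,
      sigma_u = sigma_u,
      reference_outcome = reference_outcome,
      correction_prob = correction_prob,
      rt_params = rt_params,
      race_mode = isTRUE(race_mode),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Rise-to-threshold reaction-time parameters
#'
#' Parameters of the race-style latency model: on each trial a unit's
#' activation rises linearly at rate `r ~ Normal(rate_mean, rate_sd)`
#' (truncated positive) until it reaches `threshold`; the saccade latency is
#' `onset_delay_ms + threshold / r`, clipped to the admissible 80--700 ms
#' response window. The prosaccade (error) unit rises faster on average than
#' the antisaccade (correct) unit, so errors carry shorter latencies. The
#' defaults put the median correct latency near 280 ms and the median error
#' latency near 176 ms (a ~104 ms gap), matching the pattern the cohort
#' analysis reports.
#'
#' @param rate_mean Named vector of mean rise rates (threshold units per ms)
#'   for the `correct` and `error` units.
#' @param rate_sd Named vector of rise-rate SDs (same units).
#' @param threshold Activation threshold (arbitrary positive units).
#' @param onset_delay_ms Non-decision time added to every latency.
#' @param window_ms Admissible latency window; latencies are clipped to it.
#' @return A named list of class `rt_params`.
#' @export
#' @examples
#' rt_params()$rate_mean
rt_params <- function(rate_mean = c(correct = 1 / 230, error = 1 / 126),
                      rate_sd = 0.25 * rate_mean,
                      threshold = 1,
                      onset_delay_ms = 50,
                      window_ms = c(80, 700)) {
  out <- structure(
    list(rate_mean = rate_mean, rate_sd = rate_sd, threshold = threshold,
         onset_delay_ms = onset_delay_ms, window_ms = window_ms),
    class = "rt_params"
  )
  validate_rt_params(out)
  out
}

validate_rt_params <- function(p) {
  stopifnot(is.list(p))
  if (!all(c("correct", "error") %in% names(p$rate_mean))) {
    abort("`rate_mean` must be named with 'correct' and 'error'")
  }
  if (any(p$rate_mean <= 0) || p$threshold <= 0 || p$onset_delay_ms < 0) {
    abort("rates and threshold must be positive; onset delay non-negative")
  }
  if (any(p$rate_sd < 0)) abort("`rate_sd` must be non-negative")
  if (p$window_ms[1] >= p$window_ms[2]) abort("invalid latency window")
  invisible(p)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  groups:", paste(group_levels(), x$group_sizes, collapse = ", "),
      "\n")
  cat("  trials: full =", x$n_trials_full,
      sprintf("(p = %.3f), short %d-%d", x$p_full_sequence,
              x$short_len_range[1], x$short_len_range[2]), "\n")
  cat("  logit(", x$reference_outcome, "): intercepts ",
      paste(sprintf("%+.3f", x$intercepts), collapse = " / "),
      ", slopes ", sprintf("%+.3f / %+.3f", x$slope_success, x$slope_error),
      ", sigma_u ", x$sigma_u, "\n", sep = "")
  invisible(x)
}
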