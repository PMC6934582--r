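#' Simulate a synthetic antisaccade cohort
#'
#' Generates one trial-level tibble with the statistical structure the
#' downstream analyses assume. For each participant a random intercept
#' `u ~ Normal(0, sigma_u^2)` is drawn; on each trial the logit-scale linear
#' predictor is the group intercept plus `u` plus
#' `slope_success * n_prev_success + slope_error * n_prev_fail`, where the two
#' run-length covariates count the immediately preceding consecutive correct
#' (respectively error) trials — exactly one is non-zero after trial 1, both
#' are zero on trial 1. The Bernoulli outcome is drawn from that predictor
#' (probability of the configured reference outcome); error trials are marked
#' corrected with the group's correction probability; latencies come from the
#' outcome-conditional rise-to-threshold model of [simulate_race_rt()].
#'
#' Sequence lengths: with probability `p_full_sequence` a participant
#' completes all `n_trials_full` trials, otherwise a shorter length is drawn
#' from `short_len_range` with mass `p_short_near_full` on the top three
#' lengths.
#'
#' Reproducibility: each participant has a private RNG sub-stream derived
#' from the root seed and a per-group counter, so an identical
#' (config, seed) pair yields a bit-identical cohort and cohort composition
#' is stable under changes to the other groups' sizes.
#'
#' @param config A [sim_config()].
#' @param seed Integer root seed; defaults to `config$seed`.
#' @return A tibble with one row per trial: `participant_id`, `group`, `u`,
#'   `trial_index`, `target_side`, `outcome`, `latency_ms`,
#'   `correction_latency_ms`, `n_prev_success`, `n_prev_fail`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(group_sizes = c(control = 4, mci = 3,
#'                                                      ad = 2), seed = 7))
#' dplyr::count(cohort, group)
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  groups <- group_levels()
  out <- vector("list", sum(config$group_sizes))
  k <- 0L
  for (g in seq_along(groups)) {
    for (idx in seq_len(config$group_sizes[g])) {
      k <- k + 1L
      stream <- derive_seed(seed, g * 100000 + idx)
      out[[k]] <- with_stream(stream, simulate_participant(config, groups[g],
                                                           idx))
    }
  }
  trials <- bind_rows(out)
  trials$group <- factor(trials$group, levels = groups)
  trials$outcome <- factor(trials$outcome, levels = outcome_levels())
  trials
}

simulate_participant <- function(config, group, idx) {
  n_tr <- draw_sequence_length(config)
  u <- rnorm(1, 0, config$sigma_u)
  eta0 <- config$intercepts["control"] +
    if (group == "control") 0 else config$intercepts[group]
  ref_correct <- config$reference_outcome == "correct"

  ns <- 0L; nf <- 0L
  outcome <- character(n_tr)
  latency <- numeric(n_tr)
  corr_lat <- rep(NA_real_, n_tr)
  nsv <- integer(n_tr); nfv <- integer(n_tr)
  target <- sample(c("left", "right"), n_tr, replace = TRUE)

  for (j in seq_len(n_tr)) {
    nsv[j] <- ns; nfv[j] <- nf
    eta <- eta0 + u + config$slope_success * ns + config$slope_error * nf
    p_ref <- plogis(eta)
    ref_hit <- runif(1) < p_ref
    correct <- if (ref_correct) ref_hit else !ref_hit
    if (config$race_mode) {
      # Race mode: the faster unit wins and dictates the outcome.
      rts <- c(simulate_race_rt("error", config$rt_params),
               simulate_race_rt("correct", config$rt_params))
      correct <- rts[2] < rts[1]
      latency[j] <- min(rts)
    } else {
      latency[j] <- simulate_race_rt(if (correct) "correct" else "error",
                                     config$rt_params)
    }
    if (correct) {
      outcome[j] <- "correct"
      ns <- ns + 1L; nf <- 0L
    } else {
      corrected <- runif(1) < config$correction_prob[group]
      outcome[j] <- if (corrected) "error_corrected" else "error_uncorrected"
      if (corrected) {
        # corrective saccade follows the primary after a refractory gap plus
        # a lognormal reprogramming delay (~70-200 ms after primary onset)
        corr_lat[j] <- latency[j] + 70 + exp(rnorm(1, log(60), 0.4))
      }
      nf <- nf + 1L; ns <- 0L
    }
  }
  tibble(
    participant_id = sprintf("%s%03d", toupper(substr(group, 1, 1)), idx),
    group = group,
    u = u,
    trial_index = seq_len(n_tr),
    target_side = target,
    outcome = outcome,
    latency_ms = latency,
    correction_latency_ms = corr_lat,
    n_prev_success = nsv,
    n_prev_fail = nfv
  )
}

draw_sequence_length <- function(config) {
  if (runif(1) < config$p_full_sequence) return(config$n_trials_full)
  lo <- config$short_len_range[1]; hi <- config$short_len_range[2]
  near <- seq.int(max(lo, hi - 2L), hi)
  far <- seq.int(lo, max(lo, hi - 2L) - 1L)
  if (length(far) == 0 || runif(1) < config$p_short_near_full) {
    near[sample.int(length(near), 1)]
  } else {
    far[sample.int(length(far), 1)]
  }
}

#' Simulate saccade latencies from the rise-to-threshold race model
#'
#' Latency = `onset_delay_ms + threshold / r` with rise rate
#' `r ~ Normal(rate_mean, rate_sd)` truncated to positive values, using the
#' unit matching `outcome` (the prosaccade/error unit is faster on average),
#' clipped to the admissible response window.
#'
#' @param outcome `"correct"` or `"error"` — which unit's latency to draw.
#' @param params An [rt_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of latencies in ms.
#' @export
#' @examples
#' set.seed(1)
#' median(simulate_race_rt("error", rt_params(), n = 1000))
simulate_race_rt <- function(outcome = c("correct", "error"),
                             params = rt_params(), n = 1) {
  outcome <- match.arg(outcome)
  validate_rt_params(params)
  mu <- params$rate_mean[[outcome]]
  sdv <- params$rate_sd[[outcome]]
  r <- if (sdv == 0) rep(mu, n) else {
    # inverse-CDF sampling of the positive-truncated normal
    qnorm(runif(n, pnorm(0, mu, sdv), 1), mu, sdv)
  }
  pmin(pmax(params$onset_delay_ms + params$threshold / r,
            params$window_ms[1]), params$window_ms[2])
}

# Analytic median latency of the truncated-normal rise-rate transform
# (used as an independent oracle in tests: median RT = delay + thr/median(r)).
race_rt_median <- function(outcome, params = rt_params()) {
  mu <- params$rate_mean[[outcome]]
  sdv <- params$rate_sd[[outcome]]
  a <- pnorm(0, mu, sdv)
  r_med <- qnorm((1 + a) / 2, mu, sdv)
  min(max(params$onset_delay_ms + params$threshold / r_med,
          params$window_ms[1]), params$window_ms[2])
}

#' Summarise task completion of a cohort
#'
#' @param trials Trial-level tibble (as from [simulate_cohort()]).
#' @param n_trials_full Trials in a complete sequence.
#' @return One-row tibble: participants, number and percentage with a full
#'   sequence, percentage with more than 20 trials, observed and possible
#'   trial totals.
#' @export
completion_summary <- function(trials, n_trials_full = 24) {
  per <- trials %>%
    group_by(.data$participant_id) %>%
    summarise(n_trials = max(.data$trial_index), .groups = "drop")
  tibble(
    n_participants = nrow(per),
    n_full = sum(per$n_trials == n_trials_full),
    pct_full = 100 * sum(per$n_trials == n_trials_full) / nrow(per),
    pct_over_20 = 100 * mean(per$n_trials > 20),
    n_trials_observed = sum(per$n_trials),
    n_trials_possible = nrow(per) * n_trials_full
  )
}

# Fast vectorised re-simulator used by the parametric bootstrap: regenerates
# outcome sequences (and the dynamic run-length covariates) for an existing
# cohort skeleton from given coefficients, one shared RNG stream.
resimulate_outcomes <- function(skeleton, intercepts, slope_success,
                                slope_error, sigma_u,
                                reference_outcome = "correct") {
  per <- skeleton %>%
    group_by(.data$participant_id, .data$group) %>%
    summarise(n_trials = dplyr::n(), .groups = "drop")
  npart <- nrow(per)
  u <- rnorm(npart, 0, sigma_u)
  eta0 <- intercepts["control"] +
    ifelse(per$group == "control", 0,
           intercepts[as.character(per$group)]) + u
  maxn <- max(per$n_trials)
  ns <- numeric(npart); nf <- numeric(npart)
  err_m <- matrix(FALSE, npart, maxn)
  ns_m <- matrix(0L, npart, maxn)
  nf_m <- matrix(0L, npart, maxn)
  ref_correct <- reference_outcome == "correct"
  for (j in seq_len(maxn)) {
    eta <- eta0 + slope_success * ns + slope_error * nf
    ref_hit <- runif(npart) < plogis(eta)
    correct <- if (ref_correct) ref_hit else !ref_hit
    err_m[, j] <- !correct
    ns_m[, j] <- ns
    nf_m[, j] <- nf
    ns <- ifelse(correct, ns + 1, 0)
    nf <- ifelse(correct, 0, nf + 1)
  }
  take <- cbind(rep.int(seq_len(npart), per$n_trials),
                sequence(per$n_trials))
  tibble(
    participant_id = rep(per$participant_id, per$n_trials),
    group = rep(per$group, per$n_trials),
    trial_index = sequence(per$n_trials),
    error = err_m[take],
    n_prev_success = as.integer(ns_m[take]),
    n_prev_fail = as.integer(nf_m[take])
  )
}
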