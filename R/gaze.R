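#' Classifier configuration
#'
#' Thresholds and windows for spike filtering, saccade detection and trial
#' classification. Coordinates are degrees of visual angle with the screen
#' centre at 0 and rightward positive; times are ms from target onset; the
#' target appears at +/- `target_eccentricity_deg`.
#'
#' @param velocity_spike_limit Frames whose two-sided point velocity exceeds
#'   this (deg/s) are removed as spikes (default 1500).
#' @param accel_spike_limit Acceleration spike limit in deg/s^2
#'   (default 100000).
#' @param saccade_velocity_threshold Velocity threshold (deg/s) for saccade
#'   detection (default 30).
#' @param saccade_accel_threshold Acceleration threshold (deg/s^2) used to
#'   assist onset detection (default 8000).
#' @param merge_gap_ms Saccade events separated by less than this are merged
#'   (default 20).
#' @param min_latency_ms,max_latency_ms Admissible primary-saccade latency
#'   window (defaults 80 and 700); an earlier saccade marks the trial
#'   anticipatory, none before the upper bound marks it delayed — both are
#'   excluded.
#' @param target_eccentricity_deg Target eccentricity (default 4).
#' @param correction_rule `"crossing"` (default): a correction must carry
#'   gaze across the midline into the opposite hemifield; `"reversal"`: a
#'   direction-reversed saccade suffices.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(velocity_spike_limit = 1500,
                              accel_spike_limit = 100000,
                              saccade_velocity_threshold = 30,
                              saccade_accel_threshold = 8000,
                              merge_gap_ms = 20,
                              min_latency_ms = 80,
                              max_latency_ms = 700,
                              target_eccentricity_deg = 4,
                              correction_rule = c("crossing", "reversal")) {
  correction_rule <- match.arg(correction_rule)
  stopifnot(velocity_spike_limit > 0, accel_spike_limit > 0,
            saccade_velocity_threshold > 0, saccade_accel_threshold > 0,
            min_latency_ms < max_latency_ms, min_latency_ms > 0)
  structure(as.list(environment()), class = "classifier_config")
}

#' Simulate a raw gaze trace for one classified trial
#'
#' Produces a 500 Hz sample train consistent with a trial record: fixation at
#' the screen centre, a primary saccade starting at the trial's latency with
#' a smooth raised-cosine position profile toward (error) or away from
#' (correct) the target side, an optional corrective saccade into the
#' opposite hemifield, Gaussian position noise, and optionally injected
#' single-frame spikes whose point velocity far exceeds the spike filter
#' limit.
#'
#' @param trial One-row data frame with `target_side`, `outcome`,
#'   `latency_ms` and (for corrected errors) `correction_latency_ms`.
#' @param noise_sd Gaussian position noise SD in degrees (default 0.05).
#' @param n_spikes Number of injected single-frame spikes (default 0).
#' @param spike_amplitude_deg Spike displacement in degrees (default 20).
#' @param duration_ms Trace length (default 1000 ms from target onset).
#' @param saccade_duration_ms Duration of the saccadic position ramp.
#' @param amplitude_deg Saccade amplitude (default 8: centre to +/-4 and
#'   onward past the mirror location is not modelled; the eye lands at the
#'   +/-4 deg location of the instructed or erroneous side).
#' @return Tibble of samples: `t_ms`, `x_deg`, `y_deg`.
#' @export
simulate_gaze_trial <- function(trial, noise_sd = 0.05, n_spikes = 0,
                                spike_amplitude_deg = 20,
                                duration_ms = 1000,
                                saccade_duration_ms = 40,
                                amplitude_deg = 4) {
  stopifnot(nrow(trial) == 1)
  if (trial$outcome == "excluded") abort("cannot simulate an excluded trial")
  t_ms <- seq(0, duration_ms, by = 2)
  tgt <- if (trial$target_side == "right") 1 else -1
  # primary saccade direction: toward target on errors, away on correct
  dir1 <- if (is_error_outcome(trial$outcome)) tgt else -tgt
  x <- ramp_to(t_ms, onset = trial$latency_ms, dur = saccade_duration_ms,
               from = 0, to = dir1 * amplitude_deg)
  if (trial$outcome == "error_corrected") {
    x <- x + ramp_to(t_ms, onset = trial$correction_latency_ms,
                     dur = saccade_duration_ms,
                     from = 0, to = -2 * dir1 * amplitude_deg)
  }
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  if (n_spikes > 0) {
    # keep spikes off the trace ends so the two-sided detector sees them
    ok <- seq(3, length(x) - 2)
    at <- sample(ok, n_spikes)
    x[at] <- x[at] + sample(c(-1, 1), n_spikes, TRUE) * spike_amplitude_deg
  }
  tibble(t_ms = t_ms, x_deg = x, y_deg = rep(0, length(x)))
}

# raised-cosine position ramp from `from` to `from + to` starting at `onset`
ramp_to <- function(t_ms, onset, dur, from, to) {
  s <- pmin(pmax((t_ms - onset) / dur, 0), 1)
  from + to * (1 - cos(pi * s)) / 2
}

#' Remove spike frames from a gaze trace
#'
#' Iteratively removes frames flagged as instrument spikes: a frame is a
#' spike candidate when both its backward and forward point velocities exceed
#' `velocity_spike_limit`, or its local second-difference acceleration
#' exceeds `accel_spike_limit` while the flanking frames are quiescent. At
#' each pass the single worst frame is removed and the differences are
#' recomputed over the surviving timestamps, so a burst of spikes is peeled
#' off one frame at a time and smooth saccadic motion is never touched. No
#' interpolation is performed; sample order is preserved.
#'
#' @param samples Tibble with `t_ms` and `x_deg` (time-ordered).
#' @param config A [classifier_config()].
#' @return The samples tibble with spike frames removed.
#' @export
filter_samples <- function(samples, config = classifier_config()) {
  if (nrow(samples) < 3) {
    warn("fewer than 3 samples; returning empty trace")
    return(samples[0, ])
  }
  repeat {
    n <- nrow(samples)
    if (n < 3) break
    x <- samples$x_deg
    t_s <- samples$t_ms / 1000
    vb <- c(NA, diff(x) / diff(t_s))          # backward velocity at frame i
    vf <- c(vb[-1], NA)                       # forward velocity at frame i
    v_two_sided <- pmin(abs(vb), abs(vf))     # high only for isolated spikes
    a <- abs(vf - vb) / c(NA, diff(t_s))      # local acceleration
    score <- pmax(v_two_sided / config$velocity_spike_limit,
                  a / config$accel_spike_limit, na.rm = TRUE)
    score[is.na(score)] <- 0
    # acceleration alone must not flag the neighbours of a spike: require the
    # frame's own two-sided velocity to dominate its flanks
    accel_only <- a > config$accel_spike_limit &
      v_two_sided <= config$velocity_spike_limit
    accel_only[is.na(accel_only)] <- FALSE
    flank_quiet <- v_two_sided >= pmax(c(0, v_two_sided[-n]),
                                       c(v_two_sided[-1], 0))
    bad <- (v_two_sided > config$velocity_spike_limit) |
      (accel_only & flank_quiet)
    bad[is.na(bad)] <- FALSE
    if (!any(bad)) break
    worst <- which.max(ifelse(bad, score, -Inf))
    samples <- samples[-worst, ]
  }
  samples
}

#' Detect saccadic events in a (filtered) gaze trace
#'
#' Velocity-threshold event detection: point velocities are computed by
#' central differences over the sample timestamps; contiguous runs with
#' `|v| >= saccade_velocity_threshold` define events, events separated by
#' less than `merge_gap_ms` are merged, and each event's onset/offset,
#' start/end position, peak velocity and direction are reported.
#'
#' @param samples Filtered samples (`t_ms`, `x_deg`).
#' @param config A [classifier_config()].
#' @return Tibble of events: `onset_ms`, `offset_ms`, `start_x_deg`,
#'   `end_x_deg`, `peak_velocity_deg_s`, `direction`. Zero rows when no
#'   event crosses threshold.
#' @export
detect_saccades <- function(samples, config = classifier_config()) {
  empty <- tibble(onset_ms = double(), offset_ms = double(),
                  start_x_deg = double(), end_x_deg = double(),
                  peak_velocity_deg_s = double(), direction = character())
  n <- nrow(samples)
  if (n < 3) return(empty)
  x <- samples$x_deg
  t_s <- samples$t_ms / 1000
  v <- c(0, (x[-(1:2)] - x[1:(n - 2)]) / (t_s[-(1:2)] - t_s[1:(n - 2)]), 0)
  above <- abs(v) >= config$saccade_velocity_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  if (length(idx) == 0) return(empty)
  ev <- tibble(start = starts[idx], end = ends[idx])
  # refine onsets: walk back to where velocity drops below a third of the
  # detection threshold, recovering the few ms the threshold crossing lags
  # the true movement start
  low <- config$saccade_velocity_threshold / 3
  ev$start <- vapply(ev$start, function(s) {
    s0 <- s
    while (s > 1 && s0 - s < 2 && abs(v[s - 1]) >= low &&
           abs(v[s - 1]) < abs(v[s])) {
      s <- s - 1
    }
    s
  }, numeric(1))
  # merge events separated by a short gap
  if (nrow(ev) > 1) {
    keep <- list(ev[1, ])
    for (i in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      gap_ms <- samples$t_ms[ev$start[i]] - samples$t_ms[last$end]
      if (gap_ms < config$merge_gap_ms) {
        keep[[length(keep)]]$end <- ev$end[i]
      } else {
        keep[[length(keep) + 1]] <- ev[i, ]
      }
    }
    ev <- bind_rows(keep)
  }
  purrr::pmap_dfr(ev, function(start, end) {
    i0 <- max(1, start - 1); i1 <- min(n, end + 1)
    tibble(
      onset_ms = samples$t_ms[start],
      offset_ms = samples$t_ms[end],
      start_x_deg = x[i0],
      end_x_deg = x[i1],
      peak_velocity_deg_s = max(abs(v[start:end])),
      direction = if (x[i1] >= x[i0]) "right" else "left"
    )
  })
}

#' Classify one antisaccade trial from its saccade events
#'
#' The primary saccade is the first event inside the admissible latency
#' window. An event before the lower bound marks the trial anticipatory and
#' excluded; no event by the upper bound marks it delayed and excluded. A
#' primary saccade directed toward the target is an inhibitory error; it is
#' scored corrected when a later event carries gaze across the midline into
#' the opposite hemifield (or merely reverses direction, under the
#' `"reversal"` rule). A primary saccade away from the target is correct.
#' Latency is the primary-saccade onset.
#'
#' @param events Event tibble from [detect_saccades()], time-ordered.
#' @param target_side `"left"` or `"right"`.
#' @param config A [classifier_config()].
#' @return One-row tibble: `target_side`, `outcome`, `latency_ms`,
#'   `correction_latency_ms`.
#' @export
classify_trial <- function(events, target_side,
                           config = classifier_config()) {
  if (!target_side %in% c("left", "right")) {
    abort("`target_side` must be 'left' or 'right'")
  }
  out <- function(outcome, latency = NA_real_, corr = NA_real_) {
    tibble(target_side = target_side, outcome = outcome,
           latency_ms = latency, correction_latency_ms = corr)
  }
  if (nrow(events) > 0 && any(events$onset_ms < config$min_latency_ms)) {
    return(out("excluded"))   # anticipatory
  }
  cand <- events[events$onset_ms >= config$min_latency_ms &
                   events$onset_ms <= config$max_latency_ms, ]
  if (nrow(cand) == 0) return(out("excluded"))   # delayed / no response
  primary <- cand[1, ]
  toward <- primary$direction == target_side
  if (!toward) return(out("correct", primary$onset_ms))
  later <- events[events$onset_ms > primary$offset_ms, ]
  tgt_sign <- if (target_side == "right") 1 else -1
  corrected_at <- NA_real_
  if (nrow(later) > 0) {
    hit <- if (config$correction_rule == "crossing") {
      later$end_x_deg * tgt_sign < 0
    } else {
      later$direction != target_side
    }
    if (any(hit)) corrected_at <- later$onset_ms[which(hit)[1]]
  }
  if (is.na(corrected_at)) {
    out("error_uncorrected", primary$onset_ms)
  } else {
    out("error_corrected", primary$onset_ms, corrected_at)
  }
}

#' Classify a table of gaze samples into trial records
#'
#' Runs [filter_samples()], [detect_saccades()] and [classify_trial()] over
#' every (participant, trial) in a sample-level gaze table, joining the
#' target side from a trial-level table.
#'
#' @param gaze Sample-level tibble: `participant_id`, `trial_index`, `t_ms`,
#'   `x_deg`, `y_deg`.
#' @param targets Trial-level tibble with `participant_id`, `trial_index`,
#'   `target_side` (and optionally `group`, carried through).
#' @param config A [classifier_config()].
#' @return Trial-level tibble with the same schema as [simulate_cohort()]
#'   output (minus the generator-only columns).
#' @export
classify_gaze <- function(gaze, targets, config = classifier_config()) {
  keys <- distinct(gaze, .data$participant_id, .data$trial_index)
  keys <- left_join(keys, targets, by = c("participant_id", "trial_index"))
  res <- purrr::pmap_dfr(
    list(keys$participant_id, keys$trial_index, keys$target_side),
    function(pid, tix, side) {
      tr <- gaze[gaze$participant_id == pid & gaze$trial_index == tix, ]
      ev <- detect_saccades(filter_samples(tr, config), config)
      cbind(tibble(participant_id = pid, trial_index = tix),
            classify_trial(ev, side, config))
    }
  )
  if ("group" %in% names(targets)) {
    res <- left_join(res,
                     distinct(targets, .data$participant_id, .data$group),
                     by = "participant_id") %>%
      select("participant_id", "group", dplyr::everything())
  }
  as_tibble(res)
}
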