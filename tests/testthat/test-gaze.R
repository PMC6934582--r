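flat_trace <- function(n = 200, x = 0) {
  tibble::tibble(t_ms = seq(0, by = 2, length.out = n),
                 x_deg = rep(x, n), y_deg = 0)
}

test_that("spike filter removes exactly the spiked frames", {
  tr <- flat_trace()
  # one frame displaced 4 deg: point velocity 4/0.002 = 2000 deg/s
  tr$x_deg[100] <- 4
  out <- filter_samples(tr)
  expect_equal(nrow(out), nrow(tr) - 1)
  expect_false(tr$t_ms[100] %in% out$t_ms)
  # clean trace untouched
  expect_identical(filter_samples(flat_trace()), flat_trace())
  # sub-threshold motion untouched
  slow <- flat_trace()
  slow$x_deg <- seq(0, 2, length.out = nrow(slow))
  expect_identical(filter_samples(slow), slow)
})

test_that("three injected spikes cost exactly three frames", {
  trial <- tibble::tibble(target_side = "right", outcome = "correct",
                          latency_ms = 250,
                          correction_latency_ms = NA_real_)
  set.seed(61)
  g <- simulate_gaze_trial(trial, noise_sd = 0, n_spikes = 3)
  expect_equal(nrow(g) - nrow(filter_samples(g)), 3)
})

test_that("a too-short trace is rejected with a warning", {
  expect_warning(out <- filter_samples(flat_trace(2)), "fewer than 3")
  expect_equal(nrow(out), 0)
})

test_that("saccade detection round-trips generated trials", {
  trial <- tibble::tibble(target_side = "left", outcome = "correct",
                          latency_ms = 240,
                          correction_latency_ms = NA_real_)
  g <- simulate_gaze_trial(trial, noise_sd = 0)
  ev <- detect_saccades(g)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - 240), 4 + 1e-9)
  expect_equal(ev$direction, "right")  # away from a left target

  corr <- tibble::tibble(target_side = "right", outcome = "error_corrected",
                         latency_ms = 180, correction_latency_ms = 420)
  ev2 <- detect_saccades(simulate_gaze_trial(corr, noise_sd = 0))
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$direction, c("right", "left"))

  expect_equal(nrow(detect_saccades(flat_trace())), 0)
})

test_that("trial classification follows the outcome taxonomy and latency
           window", {
  ev <- function(onset, offset, x0, x1) {
    tibble::tibble(onset_ms = onset, offset_ms = offset, start_x_deg = x0,
                   end_x_deg = x1, peak_velocity_deg_s = 200,
                   direction = ifelse(x1 >= x0, "right", "left"))
  }
  # target right, leftward primary at 250 ms -> correct
  r <- classify_trial(ev(250, 290, 0, -4), "right")
  expect_equal(r$outcome, "correct")
  expect_equal(r$latency_ms, 250)
  # anticipatory saccade -> excluded
  expect_equal(classify_trial(ev(50, 90, 0, 4), "right")$outcome, "excluded")
  # no saccade by 700 ms -> excluded
  expect_equal(classify_trial(ev(720, 760, 0, -4), "right")$outcome,
               "excluded")
  empty <- ev(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(classify_trial(empty, "left")$outcome, "excluded")
  # target left, leftward primary then rightward crossing -> corrected error
  two <- dplyr::bind_rows(ev(180, 220, 0, -4), ev(420, 460, -4, 4))
  r2 <- classify_trial(two, "left")
  expect_equal(r2$outcome, "error_corrected")
  expect_equal(r2$latency_ms, 180)
  expect_equal(r2$correction_latency_ms, 420)
  # same but the second saccade stops short of the midline -> uncorrected
  stops <- dplyr::bind_rows(ev(180, 220, 0, -4), ev(420, 460, -4, -1))
  expect_equal(classify_trial(stops, "left")$outcome, "error_uncorrected")
  # ... unless the direction-reversal rule is chosen
  cfgr <- classifier_config(correction_rule = "reversal")
  expect_equal(classify_trial(stops, "left", cfgr)$outcome,
               "error_corrected")
  expect_error(classify_trial(two, "up"), "target_side")
})

test_that("classification is invariant under left/right mirroring", {
  trials <- tibble::tibble(
    target_side = c("right", "left", "right"),
    outcome = c("correct", "error_corrected", "error_uncorrected"),
    latency_ms = c(250, 180, 300),
    correction_latency_ms = c(NA, 420, NA))
  mirror_side <- c(left = "right", right = "left")
  for (i in seq_len(nrow(trials))) {
    g <- simulate_gaze_trial(trials[i, ], noise_sd = 0)
    gm <- g
    gm$x_deg <- -gm$x_deg
    a <- classify_trial(detect_saccades(g), trials$target_side[i])
    b <- classify_trial(detect_saccades(gm),
                        mirror_side[[trials$target_side[i]]])
    expect_equal(a$outcome, b$outcome)
    expect_equal(a$latency_ms, b$latency_ms)
  }
})

test_that("noise-free cohort classification recovers labels and latencies", {
  cfg <- small_config(seed = 71)
  co <- simulate_cohort(cfg)
  gaze <- simulate_gaze_cohort(co, seed = 72, noise_sd = 0)
  cls <- classify_gaze(gaze, co %>%
                         dplyr::select(participant_id, trial_index,
                                       target_side, group))
  j <- dplyr::inner_join(co, cls, by = c("participant_id", "trial_index"),
                         suffix = c("", ".cls"))
  expect_gte(mean(as.character(j$outcome) == j$outcome.cls), 0.99)
  ok <- !is.na(j$latency_ms.cls)
  expect_lt(max(abs(j$latency_ms[ok] - j$latency_ms.cls[ok])), 4 + 1e-9)
})
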