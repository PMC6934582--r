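#' Read / write trial-level and gaze-sample CSV files
#'
#' Trial-level files carry one row per trial
#' (`participant_id, group, trial_index, target_side, outcome, latency_ms,
#' correction_latency_ms`); gaze files carry one row per 2 ms sample
#' (`participant_id, trial_index, t_ms, x_deg, y_deg`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) %>%
    mutate(group = factor(as.character(.data$group),
                          levels = group_levels()),
           outcome = factor(as.character(.data$outcome),
                            levels = outcome_levels()))
}

#' @rdname read_trials_csv
#' @param trials Trial-level tibble.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname read_trials_csv
#' @export
read_gaze_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_trials_csv
#' @param gaze Sample-level gaze tibble.
#' @export
write_gaze_csv <- function(gaze, path) {
  readr::write_csv(gaze, path)
  invisible(path)
}

#' Simulate gaze traces for a whole cohort
#'
#' @param trials Trial-level tibble from [simulate_cohort()].
#' @param seed Integer seed for trace noise.
#' @param ... Passed to [simulate_gaze_trial()].
#' @return Sample-level gaze tibble.
#' @export
simulate_gaze_cohort <- function(trials, seed = 1L, ...) {
  usable <- trials %>% filter(.data$outcome != "excluded")
  with_stream(seed, {
    purrr::pmap_dfr(
      list(usable$participant_id, usable$trial_index,
           seq_len(nrow(usable))),
      function(pid, tix, i) {
        tr <- usable[i, ]
        simulate_gaze_trial(tr, ...) %>%
          mutate(participant_id = pid, trial_index = tix, .before = 1)
      })
  })
}

#' Run the full sequential-dependence analysis pipeline
#'
#' Orchestrates every stage: obtain trial-level data (by simulation, from a
#' trial-level CSV, or by classifying a gaze CSV), compute the
#' previous-outcome and run-length tables, fit the run-length multilevel
#' model, summarise the reaction-time survival curves, and write all outputs
#' plus a reproducibility manifest to `out_dir`.
#'
#' Outputs: `trials.csv`, `table2_counts.csv`, `table2_vs_reference.csv`,
#' `table2_within_contrast.csv`, `table3.csv`, `table4.csv`, `table5.csv`,
#' `glmm_fit.json`, `manifest.json`.
#'
#' @param mode `"simulate"`, `"trial_csv"` or `"gaze_csv"`.
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()] (simulate mode).
#' @param trial_csv Path to a trial-level CSV (`trial_csv` mode, and target
#'   sides for `gaze_csv` mode).
#' @param gaze_csv Path to a sample-level gaze CSV (`gaze_csv` mode).
#' @param seed Integer seed (overrides `config$seed`).
#' @param n_quad Quadrature order for the multilevel fit.
#' @param bootstrap_reps Parametric-bootstrap replicates for the
#'   random-intercept SD interval; 0 skips the bootstrap.
#' @param response_coding Response coding for the multilevel fit.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(mode = c("simulate", "trial_csv", "gaze_csv"),
                         out_dir, config = sim_config(), trial_csv = NULL,
                         gaze_csv = NULL, seed = config$seed, n_quad = 15,
                         bootstrap_reps = 0,
                         response_coding = c("correct", "error")) {
  mode <- match.arg(mode)
  response_coding <- match.arg(response_coding)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)

  trials <- switch(
    mode,
    simulate = simulate_cohort(config, seed = seed),
    trial_csv = {
      if (is.null(trial_csv)) abort("trial_csv mode needs `trial_csv`")
      inputs <- c(inputs, trial_csv)
      read_trials_csv(trial_csv)
    },
    gaze_csv = {
      if (is.null(gaze_csv) || is.null(trial_csv)) {
        abort("gaze_csv mode needs `gaze_csv` (samples) and `trial_csv` (target sides)")
      }
      inputs <- c(inputs, gaze_csv, trial_csv)
      classify_gaze(read_gaze_csv(gaze_csv),
                    read_trials_csv(trial_csv) %>%
                      select("participant_id", "trial_index", "target_side",
                             dplyr::any_of("group")))
    })

  n_excluded <- sum(trials$outcome == "excluded")
  if (n_excluded > 0) {
    inform(sprintf("dropping %d excluded trial(s) from the analyses",
                   n_excluded))
  }

  # derived run-length covariates recomputed from the emitted sequences
  analysed <- add_run_covariates(trials)

  t2 <- seq_table2(analysed)
  t4 <- seq_table4(analysed)
  fit <- fit_glmm(analysed, ~ group + n_prev_success + n_prev_fail,
                  response_coding = response_coding, n_quad = n_quad)
  t3 <- tidy(fit)
  t5 <- rt_table5(analysed)
  ci <- if (bootstrap_reps > 0) {
    bootstrap_sigma_ci(fit, B = bootstrap_reps, seed = seed)
  } else NULL

  files <- c(
    trials = "trials.csv",
    table2_counts = "table2_counts.csv",
    table2_vs_reference = "table2_vs_reference.csv",
    table2_within_contrast = "table2_within_contrast.csv",
    table3 = "table3.csv", table4 = "table4.csv", table5 = "table5.csv",
    glmm_fit = "glmm_fit.json"
  )
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  readr::write_csv(trials %>% select(dplyr::any_of(c(
    "participant_id", "group", "trial_index", "target_side", "outcome",
    "latency_ms", "correction_latency_ms"))), paths["trials"])
  readr::write_csv(t2$counts, paths["table2_counts"])
  readr::write_csv(t2$vs_reference, paths["table2_vs_reference"])
  readr::write_csv(t2$within_contrast, paths["table2_within_contrast"])
  readr::write_csv(t3, paths["table3"])
  readr::write_csv(t4, paths["table4"])
  readr::write_csv(t5, paths["table5"])
  fit_json <- list(
    coefficients = as.list(fit$beta), se = as.list(fit$se_beta),
    sigma_u = fit$sigma_u, se_sigma_u = fit$se_sigma_u,
    loglik = fit$loglik, converged = fit$converged,
    boundary = fit$boundary, n_quad = fit$n_quad,
    response_coding = fit$response_coding,
    sigma_u_ci = if (is.null(ci)) NULL else
      list(lower = ci$lower, upper = ci$upper, B = ci$B_used)
  )
  jsonlite::write_json(fit_json, paths["glmm_fit"], auto_unbox = TRUE,
                       digits = NA, null = "null")

  manifest <- list(
    mode = mode, seed = as.integer(seed),
    config = if (mode == "simulate") {
      snap <- unclass(config)
      snap$rt_params <- lapply(unclass(snap$rt_params), unname)
      snap
    } else NULL,
    n_quad = n_quad, bootstrap_reps = bootstrap_reps,
    response_coding = response_coding,
    n_trials = nrow(trials), n_excluded = n_excluded,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(unname(paths))),
    package_version = as.character(utils::packageVersion("antiseq")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Recompute run-length covariates on a trial table
#'
#' Adds (or overwrites) `n_prev_success` / `n_prev_fail`: the number of
#' immediately preceding consecutive correct (resp. error) trials, computed
#' from the emitted outcome sequence after dropping excluded trials. Exactly
#' one of the two is non-zero after a participant's first usable trial; both
#' are zero on the first.
#'
#' @param trials Trial-level tibble.
#' @return The tibble (excluded trials dropped) with covariate columns.
#' @export
add_run_covariates <- function(trials) {
  trials %>%
    filter(.data$outcome != "excluded") %>%
    arrange(.data$participant_id, .data$trial_index) %>%
    group_by(.data$participant_id) %>%
    mutate(
      err = is_error_outcome(.data$outcome),
      run_len = preceding_run_length(.data$err),
      n_prev_success = dplyr::coalesce(
        ifelse(!lag(.data$err), .data$run_len, 0L), 0L),
      n_prev_fail = dplyr::coalesce(
        ifelse(lag(.data$err), .data$run_len, 0L), 0L)
    ) %>%
    ungroup() %>%
    select(-"err", -"run_len")
}
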