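#' Kaplan-Meier curve of saccade reaction times
#'
#' Product-limit estimate of `S(t) = P(latency > t)` — here the "event" is
#' the first saccade, so `S(t)` is the fraction of trials yet to record a
#' response at time `t`. Latencies inside the admissible response window are
#' always observed events, so censoring is structurally absent in this
#' design; censor flags are accepted for generality. The median is the
#' smallest time with `S(t) <= 0.5`; its confidence interval uses the
#' log-log (Brookmeyer-Crowley-style) transform.
#'
#' @param latencies Positive latencies in ms.
#' @param censored Logical vector, `TRUE` where the latency is
#'   right-censored (default: none).
#' @param level Confidence level (default 0.95).
#' @return An object of class `ast_km`: list with `curve` (tibble `time`,
#'   `n_risk`, `n_event`, `survival`, `lower`, `upper`), `median`,
#'   `median_lower`, `median_upper`, `n`.
#' @export
#' @examples
#' km <- km_curve(c(100, 200, 300))
#' km$curve$survival
km_curve <- function(latencies, censored = rep(FALSE, length(latencies)),
                     level = 0.95) {
  if (length(latencies) == 0) abort("empty latency vector")
  stopifnot(all(latencies > 0), length(censored) == length(latencies))
  sf <- survival::survfit(
    survival::Surv(latencies, !censored) ~ 1,
    conf.type = "log-log", conf.int = level)
  tab <- summary(sf)$table
  curve <- tibble(time = sf$time, n_risk = sf$n.risk,
                  n_event = sf$n.event, survival = sf$surv,
                  lower = sf$lower, upper = sf$upper)
  # median convention: smallest event time with S(t) <= 0.5 (survfit
  # averages the two central times when S hits 0.5 exactly)
  med <- if (any(curve$survival <= 0.5)) {
    min(curve$time[curve$survival <= 0.5])
  } else NA_real_
  structure(
    list(
      curve = curve,
      median = med,
      median_lower = unname(tab[grep("LCL$", names(tab))]),
      median_upper = unname(tab[grep("UCL$", names(tab))]),
      n = length(latencies)
    ),
    class = "ast_km"
  )
}

#' @export
print.ast_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, median = %g ms (%g-%g)\n",
              x$n, x$median, x$median_lower, x$median_upper))
  invisible(x)
}

#' Kaplan-Meier reaction-time curves by group and trial outcome
#'
#' Binarizes trial outcomes (correct vs error, corrected or not) and fits a
#' Kaplan-Meier curve per group x outcome stratum.
#'
#' @param trials Trial-level tibble with `group`, `outcome`, `latency_ms`;
#'   excluded trials are dropped.
#' @return Tibble: `group`, `initial_event` (correct/error), `n`, `median`,
#'   `median_lower`, `median_upper`, and a list-column `curve` of per-stratum
#'   step functions.
#' @export
km_by_group <- function(trials) {
  dat <- trials %>%
    filter(.data$outcome != "excluded", !is.na(.data$latency_ms)) %>%
    mutate(initial_event = ifelse(is_error_outcome(.data$outcome),
                                  "error", "correct"))
  dat %>%
    group_by(.data$group, .data$initial_event) %>%
    summarise(km = list(km_curve(.data$latency_ms)), .groups = "drop") %>%
    mutate(n = purrr::map_int(.data$km, "n"),
           median = purrr::map_dbl(.data$km, "median"),
           median_lower = purrr::map_dbl(.data$km, "median_lower"),
           median_upper = purrr::map_dbl(.data$km, "median_upper"),
           curve = purrr::map(.data$km, "curve")) %>%
    select(-"km")
}

#' Welch two-sample t-test of log reaction times
#'
#' Natural-log transforms the latencies (reducing their right skew) and
#' compares error against correct trials with a Welch t-test
#' (Satterthwaite df). Also reports the pooled-SD standardised mean
#' difference on the log scale and the variance explained
#' `r_squared = t^2 / (t^2 + df)`.
#'
#' The t statistic is signed as error minus correct, so faster errors give a
#' negative t.
#'
#' @param correct_latencies,error_latencies Positive latencies (ms), at
#'   least 2 each.
#' @return One-row tibble: `t`, `df`, `p`, `cohen_d`, `r_squared`,
#'   `mean_log_correct`, `mean_log_error`.
#' @export
#' @examples
#' welch_log_rt(c(250, 280, 300, 310), c(150, 170, 180, 200))
welch_log_rt <- function(correct_latencies, error_latencies) {
  if (any(c(correct_latencies, error_latencies) <= 0)) {
    abort("latencies must be positive")
  }
  if (length(correct_latencies) < 2 || length(error_latencies) < 2) {
    abort("need >= 2 observations per sample")
  }
  lc <- log(correct_latencies); le <- log(error_latencies)
  tt <- t.test(le, lc, var.equal = FALSE)
  n1 <- length(le); n2 <- length(lc)
  sp <- sqrt(((n1 - 1) * stats::var(le) + (n2 - 1) * stats::var(lc)) /
               (n1 + n2 - 2))
  d <- (mean(lc) - mean(le)) / sp
  tval <- unname(tt$statistic); dfv <- unname(tt$parameter)
  tibble(t = tval, df = dfv, p = unname(tt$p.value), cohen_d = d,
         r_squared = tval^2 / (tval^2 + dfv),
         mean_log_correct = mean(lc), mean_log_error = mean(le))
}

#' Median-latency table by group and initial event
#'
#' @inheritParams km_by_group
#' @return Tibble: `group`, `initial_event`, `n`, `median`, `median_lower`,
#'   `median_upper`.
#' @export
rt_table5 <- function(trials) {
  km_by_group(trials) %>%
    select("group", "initial_event", "n", "median", "median_lower",
           "median_upper")
}

#' Plot Kaplan-Meier reaction-time curves by group and outcome
#'
#' @inheritParams km_by_group
#' @return A ggplot object: survivor step functions, colour = group,
#'   linetype = initial event.
#' @export
plot_km_curves <- function(trials) {
  curves <- km_by_group(trials) %>%
    select("group", "initial_event", "curve") %>%
    tidyr::unnest("curve")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group,
                                       linetype = .data$initial_event)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "reaction time (ms)",
                  y = "proportion yet to respond",
                  colour = "group", linetype = "initial event") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ast_km <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dotted") +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dotted") +
    ggplot2::labs(x = "reaction time (ms)",
                  y = "proportion yet to respond") +
    ggplot2::theme_minimal()
}
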