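#' Error counts conditioned on the previous trial's outcome
#'
#' For every usable (non-excluded) trial after a participant's first, tallies
#' whether the current trial is an inhibitory error (corrected and
#' uncorrected errors both count as errors on the current side), stratified
#' by group and by the *previous* trial's three-way outcome. Excluded trials
#' are dropped before pairing, so pairing runs over the surviving adjacency;
#' each participant's first usable trial conditions nothing; participants
#' with fewer than two usable trials contribute nothing.
#'
#' @param trials Trial-level tibble with `participant_id`, `group`,
#'   `trial_index`, `outcome`.
#' @return Tibble: `group`, `condition` (prev_correct /
#'   prev_error_corrected / prev_error_uncorrected), `errors`, `total`,
#'   `proportion`, `se`.
#' @export
#' @examples
#' tr <- tibble::tibble(participant_id = "P1", group = "control",
#'                      trial_index = 1:4,
#'                      outcome = c("correct", "error_corrected",
#'                                  "error_uncorrected", "correct"))
#' condition_on_previous(tr)
condition_on_previous <- function(trials) {
  usable <- trials %>%
    filter(.data$outcome != "excluded") %>%
    arrange(.data$participant_id, .data$trial_index) %>%
    group_by(.data$participant_id)
  paired <- usable %>%
    mutate(prev_outcome = lag(as.character(.data$outcome))) %>%
    ungroup() %>%
    filter(!is.na(.data$prev_outcome))
  paired %>%
    mutate(condition = factor(
      case_when(
        .data$prev_outcome == "correct" ~ "prev_correct",
        .data$prev_outcome == "error_corrected" ~ "prev_error_corrected",
        TRUE ~ "prev_error_uncorrected"
      ),
      levels = c("prev_error_uncorrected", "prev_error_corrected",
                 "prev_correct")
    )) %>%
    group_by(.data$group, .data$condition, .drop = FALSE) %>%
    summarise(errors = sum(is_error_outcome(.data$outcome)),
              total = dplyr::n(), .groups = "drop") %>%
    mutate(proportion = ifelse(.data$total > 0,
                               .data$errors / .data$total, NA_real_),
           se = ifelse(.data$total > 0,
                       proportion_se(.data$errors, pmax(.data$total, 1)),
                       NA_real_))
}

#' Error counts conditioned on the preceding run length
#'
#' For every usable trial after a participant's first, computes the maximal
#' run of identical binarized outcomes (correct vs error) ending at the
#' previous trial, bins lengths of 6 or more as `"6+"`, and tallies
#' current-trial errors per group, run type and length bin.
#'
#' @inheritParams condition_on_previous
#' @return Tibble: `group`, `run_type` (correct/error), `length_bin`
#'   (1..5, 6+), `errors`, `total`, `proportion`, `se`.
#' @export
run_lengths <- function(trials) {
  usable <- trials %>%
    filter(.data$outcome != "excluded") %>%
    arrange(.data$participant_id, .data$trial_index)
  per <- usable %>%
    group_by(.data$participant_id) %>%
    mutate(err = is_error_outcome(.data$outcome),
           run_len = preceding_run_length(.data$err),
           run_type = ifelse(lag(.data$err), "error", "correct")) %>%
    ungroup() %>%
    filter(!is.na(.data$run_type))
  per %>%
    mutate(length_bin = factor(ifelse(.data$run_len >= 6, "6+",
                                      as.character(.data$run_len)),
                               levels = c("1", "2", "3", "4", "5", "6+")),
           run_type = factor(.data$run_type,
                             levels = c("correct", "error"))) %>%
    group_by(.data$group, .data$run_type, .data$length_bin, .drop = FALSE) %>%
    summarise(errors = sum(.data$err), total = dplyr::n(),
              .groups = "drop") %>%
    mutate(proportion = ifelse(.data$total > 0,
                               .data$errors / .data$total, NA_real_),
           se = ifelse(.data$total > 0,
                       proportion_se(.data$errors, pmax(.data$total, 1)),
                       NA_real_))
}

# length of the maximal run of identical values ending at the previous
# element; NA for the first element
preceding_run_length <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  run <- integer(n)
  run[1] <- 1L
  for (j in seq_len(n)[-1]) {
    run[j] <- if (x[j] == x[j - 1]) run[j - 1] + 1L else 1L
  }
  c(NA_integer_, run[-n])
}

#' Reconstruct a cell total from a printed error count and proportion
#'
#' Published contingency tables often print the number of errors and the
#' proportion (to three digits of the fraction) but not the denominator.
#' This inverts the pair: the candidate is `round(errors / proportion)`,
#' verified by checking that `errors / n` reproduces the printed proportion
#' at its printed precision; candidates within +/-2 are searched, and if
#' none reproduces it the closest is returned with a warning.
#'
#' @param errors Integer error count.
#' @param proportion Printed proportion as a 3-digit fraction (e.g. 0.815
#'   for a printed 81.5\%).
#' @param digits Printed precision of the fraction (default 3).
#' @return Integer total.
#' @export
#' @examples
#' reconstruct_total(123, 0.815)  # 151
reconstruct_total <- function(errors, proportion, digits = 3) {
  if (proportion <= 0 || proportion >= 1) {
    abort("`proportion` must be strictly between 0 and 1")
  }
  n0 <- round(errors / proportion)
  cand <- unique(pmax(n0 + (-2:2), errors))
  ok <- cand[round(errors / cand, digits) == round(proportion, digits)]
  if (length(ok) == 0) {
    warn(sprintf(
      "no total near %d reproduces %.*f; returning the closest", n0,
      digits, proportion))
    return(as.integer(n0))
  }
  as.integer(ok[which.min(abs(ok - errors / proportion))])
}

#' Binomial standard error of a sample proportion
#'
#' `sqrt(p(1-p)/n)` at the observed proportion.
#'
#' @param errors Numerator count(s).
#' @param total Denominator(s), positive.
#' @return Numeric SE(s).
#' @export
proportion_se <- function(errors, total) {
  stopifnot(all(total > 0))
  p <- errors / total
  sqrt(p * (1 - p) / total)
}

#' Log-odds ratio between two binomial conditions
#'
#' Compares errors `a` (vs non-errors `b`) in condition 1 against errors `c`
#' (vs non-errors `d`) in condition 2: estimate `ln(a/b) - ln(c/d)`, SE
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, Wald Z and normal p-value. Any zero cell
#' triggers the Haldane-Anscombe +0.5 correction on all four cells, with a
#' warning.
#'
#' @param a,b Errors and non-errors in condition 1.
#' @param c,d Errors and non-errors in condition 2.
#' @param tails `"two"` (default) or `"one"`.
#' @param comparison Optional text label carried into the result.
#' @return One-row tibble: `comparison`, `estimate`, `se`, `z`, `p`,
#'   `tails`, `corrected` (logical, continuity correction applied).
#' @export
#' @examples
#' log_odds_ratio(123, 28, 262, 120)
log_odds_ratio <- function(a, b, c, d, tails = c("two", "one"),
                           comparison = NA_character_) {
  tails <- match.arg(tails)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    warn("zero cell: applying Haldane-Anscombe +0.5 correction")
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- log(a / b) - log(c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- est / se
  p <- if (tails == "two") 2 * pnorm(-abs(z)) else pnorm(-abs(z))
  tibble(comparison = comparison, estimate = est, se = se, z = z, p = p,
         tails = tails, corrected = corrected)
}

#' One-sample Wald Z-test for a proportion
#'
#' Tests an observed proportion against `p0` (default 0.5, chance). The
#' default variance is evaluated at the *observed* proportion,
#' `z = (p_hat - p0) / sqrt(p_hat (1 - p_hat) / n)`; set
#' `variance = "null"` for the p0-variance variant.
#'
#' @param p_hat Observed proportion, strictly inside (0, 1).
#' @param n Number of observations.
#' @param p0 Null value (default 0.5).
#' @param tails `"one"` (default) or `"two"`.
#' @param variance `"observed"` (default) or `"null"`.
#' @return One-row tibble: `comparison`, `estimate` (p_hat - p0), `se`, `z`,
#'   `p`, `tails`.
#' @export
#' @examples
#' wald_one_sample(140 / 418, 418)
wald_one_sample <- function(p_hat, n, p0 = 0.5, tails = c("one", "two"),
                            variance = c("observed", "null")) {
  tails <- match.arg(tails)
  variance <- match.arg(variance)
  if (p_hat <= 0 || p_hat >= 1) {
    abort("`p_hat` must be strictly between 0 and 1")
  }
  stopifnot(n > 0)
  pv <- if (variance == "observed") p_hat else p0
  se <- sqrt(pv * (1 - pv) / n)
  z <- (p_hat - p0) / se
  p <- if (tails == "two") 2 * pnorm(-abs(z)) else pnorm(-abs(z))
  tibble(comparison = sprintf("p vs %.3g", p0), estimate = p_hat - p0,
         se = se, z = z, p = p, tails = tails)
}

#' Pearson chi-squared test of independence with Cramer's V
#'
#' @param table An r x c matrix of counts (all expected counts must be
#'   positive).
#' @return One-row tibble: `statistic`, `df`, `p`, `cramers_v`, `n`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (any(dim(table) < 2) || any(rowSums(table) == 0) ||
      any(colSums(table) == 0)) {
    abort("degenerate table: need >= 2 rows and columns with positive margins")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  n <- sum(table)
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value),
         cramers_v = sqrt(unname(ct$statistic) /
                            (n * (min(dim(table)) - 1))),
         n = n)
}

#' Previous-outcome summary table with group and within-group contrasts
#'
#' Builds the previous-outcome conditioning table for a cohort: per group
#' and previous-trial condition the error count, total, proportion and
#' binomial SE; the log-odds ratio of each patient group relative to the
#' control group within each condition; and the within-group contrast of
#' error probability after an uncorrected versus a corrected previous error.
#'
#' @inheritParams condition_on_previous
#' @param reference_group Group against which the between-group log-odds are
#'   taken (default `"control"`).
#' @return A list of tibbles: `counts`, `vs_reference`, `within_contrast`.
#' @export
seq_table2 <- function(trials, reference_group = "control") {
  counts <- condition_on_previous(trials)
  ref <- counts %>% filter(.data$group == reference_group)
  vs_ref <- counts %>%
    filter(.data$group != reference_group) %>%
    left_join(ref %>% select("condition", ref_errors = "errors",
                             ref_total = "total"),
              by = "condition") %>%
    purrr::pmap_dfr(function(group, condition, errors, total, proportion,
                             se, ref_errors, ref_total) {
      log_odds_ratio(errors, total - errors, ref_errors,
                     ref_total - ref_errors,
                     comparison = sprintf("%s vs %s | %s", group,
                                          reference_group, condition)) %>%
        mutate(group = group, condition = condition, .before = 1)
    })
  within <- counts %>%
    select("group", "condition", "errors", "total") %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("errors", "total")) %>%
    purrr::pmap_dfr(function(group, errors_prev_error_uncorrected,
                             errors_prev_error_corrected, errors_prev_correct,
                             total_prev_error_uncorrected,
                             total_prev_error_corrected, total_prev_correct) {
      log_odds_ratio(
        errors_prev_error_uncorrected,
        total_prev_error_uncorrected - errors_prev_error_uncorrected,
        errors_prev_error_corrected,
        total_prev_error_corrected - errors_prev_error_corrected,
        comparison = sprintf("%s: Error-c vs Error+c", group)) %>%
        mutate(group = group, .before = 1)
    })
  list(counts = counts, vs_reference = vs_ref, within_contrast = within)
}

#' Run-length proportion table with significance stars
#'
#' Per group and run type, the error proportion at each preceding run length
#' with two-tailed log-odds-ratio tests of each length bin against the
#' length-1 bin, starred at the 5\% (*) and 1\% (**) levels.
#'
#' @inheritParams condition_on_previous
#' @return Tibble: the [run_lengths()] columns plus `z_vs_len1`, `p_vs_len1`
#'   and `stars`.
#' @export
seq_table4 <- function(trials) {
  rl <- run_lengths(trials)
  base <- rl %>% filter(.data$length_bin == "1") %>%
    select("group", "run_type", base_errors = "errors",
           base_total = "total")
  rl %>%
    left_join(base, by = c("group", "run_type")) %>%
    mutate(stats = purrr::pmap(
      list(.data$errors, .data$total, .data$base_errors, .data$base_total,
           .data$length_bin),
      function(e, t, be, bt, bin) {
        if (bin == "1" || t == 0 || bt == 0) {
          return(tibble(z = NA_real_, p = NA_real_))
        }
        lor <- suppressWarnings(log_odds_ratio(e, t - e, be, bt - be))
        tibble(z = lor$z, p = lor$p)
      })) %>%
    tidyr::unnest("stats") %>%
    mutate(stars = case_when(is.na(.data$p) ~ "",
                             .data$p < 0.01 ~ "**",
                             .data$p < 0.05 ~ "*",
                             TRUE ~ "")) %>%
    rename(z_vs_len1 = "z", p_vs_len1 = "p") %>%
    select(-"base_errors", -"base_total")
}
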