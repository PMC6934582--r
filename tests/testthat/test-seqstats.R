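one_participant <- function(outcomes, group = "control", id = "P1") {
  tibble::tibble(participant_id = id, group = group,
                 trial_index = seq_along(outcomes), outcome = outcomes)
}

test_that("previous-outcome conditioning matches hand enumeration", {
  tr <- one_participant(c("correct", "error_corrected", "error_uncorrected",
                          "correct"))
  cc <- condition_on_previous(tr)
  get <- function(cond) cc[cc$condition == cond, ]
  expect_equal(get("prev_correct")$errors, 1)          # trial 2
  expect_equal(get("prev_correct")$total, 1)
  expect_equal(get("prev_error_corrected")$errors, 1)  # trial 3
  expect_equal(get("prev_error_corrected")$total, 1)
  expect_equal(get("prev_error_uncorrected")$errors, 0) # trial 4
  expect_equal(get("prev_error_uncorrected")$total, 1)
})

test_that("an all-correct sequence conditions only on previous-correct", {
  n <- 9
  cc <- condition_on_previous(one_participant(rep("correct", n)))
  expect_equal(cc$errors[cc$condition == "prev_correct"], 0)
  expect_equal(cc$total[cc$condition == "prev_correct"], n - 1)
  expect_equal(sum(cc$total), n - 1)
})

test_that("excluded trials leave all conditioning denominators", {
  tr <- one_participant(c("correct", "excluded", "error_corrected",
                          "correct"))
  cc <- condition_on_previous(tr)
  # exclusion removed before pairing: correct -> error_corrected -> correct
  expect_equal(sum(cc$total), 2)
  expect_equal(cc$errors[cc$condition == "prev_correct"], 1)
  # a participant with < 2 usable trials contributes nothing
  lone <- one_participant(c("correct", "excluded"))
  expect_equal(sum(condition_on_previous(lone)$total), 0)
})

test_that("conditioning totals are conserved over a full cohort", {
  co <- cohort_202()
  cc <- condition_on_previous(co)
  expected <- co %>%
    dplyr::filter(outcome != "excluded") %>%
    dplyr::count(participant_id) %>%
    dplyr::summarise(tot = sum(n - 1)) %>%
    dplyr::pull(tot)
  expect_equal(sum(cc$total), expected)
})

test_that("run-length tallies follow the maximal-run definition", {
  rl <- run_lengths(one_participant(c("correct", "correct",
                                      "error_uncorrected")))
  hit <- rl[rl$run_type == "correct" & rl$length_bin == "2", ]
  expect_equal(hit$errors, 1)   # trial 3 is an error after a 2-run
  expect_equal(hit$total, 1)
  expect_equal(rl$total[rl$run_type == "correct" & rl$length_bin == "1"], 1)

  rl2 <- run_lengths(one_participant(rep("error_corrected", 3)))
  expect_equal(rl2$total[rl2$run_type == "error" & rl2$length_bin == "1"], 1)
  expect_equal(rl2$total[rl2$run_type == "error" & rl2$length_bin == "2"], 1)
  expect_equal(sum(rl2$errors), 2)

  # lengths of 6 and beyond share the 6+ bin
  rl3 <- run_lengths(one_participant(c(rep("correct", 9),
                                       "error_uncorrected")))
  expect_equal(sum(rl3$total[rl3$length_bin == "6+"]), 4)
})

test_that("zero-slope cohorts show flat error proportions across run
           lengths", {
  cfg <- sim_config(group_sizes = c(control = 300, mci = 1, ad = 1),
                    p_full_sequence = 1, sigma_u = 0, slope_success = 0,
                    slope_error = 0, seed = 81)
  rl <- run_lengths(simulate_cohort(cfg)) %>%
    dplyr::filter(group == "control", total > 20)
  p0 <- 1 - plogis(0.741)
  for (i in seq_len(nrow(rl))) {
    se <- sqrt(p0 * (1 - p0) / rl$total[i])
    expect_lt(abs(rl$proportion[i] - p0), 3 * se)
  }
})

test_that("positive error-run dependence yields increasing error
           proportions with error-run length", {
  cfg <- sim_config(group_sizes = c(control = 400, mci = 1, ad = 1),
                    p_full_sequence = 1, sigma_u = 0.5, slope_error = -0.5,
                    seed = 82)
  rl <- run_lengths(simulate_cohort(cfg)) %>%
    dplyr::filter(group == "control", run_type == "error", total > 10)
  for (i in seq_len(nrow(rl))[-1]) {
    slack <- 2 * sqrt(rl$se[i]^2 + rl$se[i - 1]^2)
    expect_gt(rl$proportion[i], rl$proportion[i - 1] - slack)
  }
  expect_gt(rl$proportion[nrow(rl)], rl$proportion[1])
})

test_that("cell totals are reconstructed from printed counts and
           proportions", {
  expect_equal(reconstruct_total(262, 0.686), 382L)
  expect_equal(reconstruct_total(123, 0.815), 151L)
  expect_equal(reconstruct_total(100, 0.500), 200L)
  expect_error(reconstruct_total(10, 0), "between 0 and 1")
  expect_error(reconstruct_total(10, 1), "between 0 and 1")
  expect_warning(reconstruct_total(100, 0.997), "closest")
})

test_that("reconstruction inverts 3-digit rounding wherever the pair is
           identifiable", {
  for (n in c(7, 23, 57, 151, 382, 418, 598, 631, 1044, 1363, 1999)) {
    for (p_true in c(0.1, 0.335, 0.5, 0.815)) {
      e <- round(p_true * n)
      if (e <= 0 || e >= n) next
      printed <- round(e / n, 3)
      if (printed <= 0 || printed >= 1) next
      # identifiability: unique candidate in the +/-2 window
      cand <- round(e / printed) + (-2:2)
      cand <- cand[cand >= e]
      matches <- cand[round(e / cand, 3) == printed]
      got <- reconstruct_total(e, printed)
      expect_equal(round(e / got, 3), printed)
      if (length(matches) == 1) expect_equal(got, as.integer(n))
    }
  }
})

test_that("proportion SEs reproduce the published precision", {
  expect_equal(round(proportion_se(123, 151), 3), 0.032)
  expect_equal(round(proportion_se(141, 186), 3), 0.031)
  expect_equal(proportion_se(0, 50), 0)
})

test_that("log-odds ratios match reconstructed published contrasts", {
  ad <- log_odds_ratio(123, 28, 262, 120)
  expect_lt(abs(ad$estimate - 0.699), 0.01)
  expect_lt(abs(ad$se - 0.237), 0.01)
  expect_lt(abs(ad$z - 2.954), 0.05)
  ctl <- log_odds_ratio(78, 53, 362, 269)
  expect_lt(abs(ctl$estimate - 0.089), 0.01)
  expect_lt(abs(ctl$se - 0.195), 0.01)
  expect_lt(abs(ctl$z - 0.458), 0.05)
  eq <- log_odds_ratio(10, 10, 10, 10)
  expect_equal(eq$estimate, 0)
  expect_equal(eq$z, 0)
})

test_that("log-odds ratio is antisymmetric and handles zero cells", {
  set.seed(91)
  for (i in 1:25) {
    cell <- sample(1:400, 4)
    a <- log_odds_ratio(cell[1], cell[2], cell[3], cell[4])
    b <- log_odds_ratio(cell[3], cell[4], cell[1], cell[2])
    expect_equal(a$estimate, -b$estimate)
    expect_equal(a$se, b$se)
    expect_equal(a$p, b$p)
  }
  expect_warning(z <- log_odds_ratio(0, 10, 5, 5), "Haldane")
  expect_true(is.finite(z$estimate) && z$corrected)
})

test_that("one-sample Wald Z uses observed-proportion variance", {
  expect_lt(abs(wald_one_sample(0.335, 418)$z - -7.147), 0.05)
  expect_lt(abs(wald_one_sample(260 / 668, 668)$z - -5.87), 0.05)
  expect_equal(wald_one_sample(0.5, 123)$z, 0)
  # the null-variance variant is different (and not the published one)
  expect_false(isTRUE(all.equal(
    wald_one_sample(0.335, 418, variance = "null")$z, -7.147,
    tolerance = 0.01)))
  expect_error(wald_one_sample(0, 10), "strictly between")
})

test_that("chi-squared independence matches the direct formula oracle", {
  flat <- chisq_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$cramers_v, 0)
  perfect <- chisq_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$cramers_v, 1)
  set.seed(92)
  tab <- matrix(sample(5:60, 12), 3, 4)
  got <- chisq_independence(tab)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_counts)^2 / exp_counts)
  expect_equal(got$statistic, stat)
  expect_equal(got$df, 6)
  expect_equal(got$cramers_v, sqrt(stat / (sum(tab) * 2)))
  expect_error(chisq_independence(matrix(c(1, 1), 2, 1)), "degenerate")
})

test_that("summary tables assemble counts, contrasts and stars", {
  co <- cohort_202()
  t2 <- seq_table2(co)
  expect_equal(nrow(t2$counts), 9)
  expect_equal(nrow(t2$vs_reference), 6)
  expect_equal(nrow(t2$within_contrast), 3)
  # within-group contrast equals a direct call on the same cells
  cc <- t2$counts
  ad_unc <- cc[cc$group == "ad" & cc$condition == "prev_error_uncorrected", ]
  ad_cor <- cc[cc$group == "ad" & cc$condition == "prev_error_corrected", ]
  direct <- log_odds_ratio(ad_unc$errors, ad_unc$total - ad_unc$errors,
                           ad_cor$errors, ad_cor$total - ad_cor$errors)
  expect_equal(t2$within_contrast$estimate[t2$within_contrast$group == "ad"],
               direct$estimate)
  t4 <- seq_table4(co)
  expect_equal(nrow(t4), 36)
  expect_true(all(t4$stars[t4$length_bin == "1"] == ""))
  expect_true(all(t4$stars %in% c("", "*", "**")))
})
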