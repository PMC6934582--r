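test_that("marginal log-likelihood matches brute-force grid integration on a
           tiny dataset", {
  dat <- tiny_glmm_data()
  mf <- antiseq:::prepare_glmm_frame(
    dat, ~ group + n_prev_success + n_prev_fail, "correct")
  gh <- pracma::gaussHermite(15)
  for (par in list(c(0.5, -0.2, -0.3, 0.05, -0.04, 1.2),
                   c(0, 0, 0, 0, 0, 0.4),
                   c(1.5, -1, 0.5, 0.2, -0.3, 2.5))) {
    agq <- -antiseq:::glmm_nll_cpp(par, mf$X, mf$y, mf$start_idx, mf$len,
                                   gh$x, gh$w)
    grid <- grid_loglik(par[1:5], par[6], mf$X, mf$y,
                        mf$data$participant_id)
    expect_equal(agq, grid, tolerance = 1e-6)
  }
})

test_that("quadrature order is converged at the default node count", {
  co <- cohort_202()
  fit <- fit_glmm(co)
  mf <- antiseq:::prepare_glmm_frame(co, fit$fixed, "correct")
  par <- c(fit$beta, fit$sigma_u)
  ll <- sapply(c(15, 41), function(k) {
    gh <- pracma::gaussHermite(k)
    -antiseq:::glmm_nll_cpp(par, mf$X, mf$y, mf$start_idx, mf$len,
                            gh$x, gh$w)
  })
  expect_lt(abs(ll[1] - ll[2]), 1e-6)
})

test_that("a zero-variance cohort reduces to the logistic-regression
           oracle", {
  cfg <- sim_config(group_sizes = c(control = 40, mci = 25, ad = 20),
                    sigma_u = 0, seed = 112)
  co <- simulate_cohort(cfg)
  fit <- fit_glmm(co)
  oracle <- glm(I(outcome == "correct") ~ group + n_prev_success +
                  n_prev_fail, binomial(), data = co)
  expect_true(fit$boundary)
  expect_lt(fit$sigma_u, 0.01)
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
  # the quadrature path agrees with the degenerate-likelihood limit
  mf <- antiseq:::prepare_glmm_frame(co, fit$fixed, "correct")
  gh <- pracma::gaussHermite(15)
  nll <- antiseq:::glmm_nll_cpp(c(coef(oracle), 1e-6), mf$X, mf$y,
                                mf$start_idx, mf$len, gh$x, gh$w)
  expect_equal(-nll, as.numeric(logLik(oracle)), tolerance = 1e-6)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  co <- cohort_202()
  fit <- fit_glmm(co)
  d <- fit$data
  d$yy <- fit$y
  m <- lme4::glmer(yy ~ group + n_prev_success + n_prev_fail +
                     (1 | participant_id), data = d,
                   family = stats::binomial(), nAGQ = 15)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(fit$sigma_u,
               sqrt(unname(unlist(lme4::VarCorr(m)))), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-4)
})

test_that("the likelihood is invariant under response-coding flips", {
  cfg <- small_config(seed = 112)
  co <- simulate_cohort(cfg)
  a <- fit_glmm(co, response_coding = "correct")
  b <- fit_glmm(co, response_coding = "error")
  expect_equal(a$loglik, b$loglik, tolerance = 1e-6)
  expect_equal(unname(a$beta), -unname(b$beta), tolerance = 1e-4)
  expect_equal(a$sigma_u, b$sigma_u, tolerance = 1e-4)
})

test_that("deviance tests behave at the null and reject junk nesting", {
  co <- simulate_cohort(small_config(seed = 113))
  full <- fit_glmm(co)
  expect_equal(deviance_test(full, full)$statistic, 0)
  expect_equal(deviance_test(full, full)$p, 1)
  red <- fit_glmm(co, ~ group)
  dt <- deviance_test(full, red)
  expect_equal(dt$df, 2)
  expect_gte(dt$statistic, 0)
  expect_error(deviance_test(red, full), "nested")
  other <- fit_glmm(co, ~ n_prev_success)
  expect_error(deviance_test(full, fit_glmm(co, ~ u)), "nested")
})

test_that("the null deviance statistic is chi-squared calibrated", {
  # simulate under the reduced model, test the two run-length slopes
  stats <- sapply(1:100, function(s) {
    cfg <- sim_config(group_sizes = c(control = 12, mci = 9, ad = 9),
                      n_trials_full = 8, short_len_range = c(4L, 7L),
                      slope_success = 0, slope_error = 0, sigma_u = 1,
                      seed = 1000 + s)
    co <- simulate_cohort(cfg)
    full <- fit_glmm(co, compute_vcov = FALSE)
    red <- fit_glmm(co, ~ group, compute_vcov = FALSE)
    deviance_test(full, red)$statistic
  })
  ks <- suppressWarnings(
    stats::ks.test(stats, function(q) stats::pchisq(q, df = 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the random intercept is decisively supported when present", {
  co <- cohort_202()
  full <- fit_glmm(co)
  red <- fit_glmm(co, random_intercept = FALSE)
  dt <- suppressMessages(deviance_test(full, red))
  expect_equal(dt$df, 1)
  expect_gt(dt$statistic, 100)
  expect_lt(dt$p, 1e-10)
})

test_that("bootstrap interval is seeded, validated, and covers the truth at
           small scale", {
  co <- simulate_cohort(small_config(seed = 114))
  fit <- fit_glmm(co)
  expect_error(bootstrap_sigma_ci(fit, B = 0), "positive")
  ci1 <- bootstrap_sigma_ci(fit, B = 12, seed = 5)
  ci2 <- bootstrap_sigma_ci(fit, B = 12, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1$lower, ci1$upper)

  # coverage at reduced B over independent replicate cohorts
  cover <- sapply(1:25, function(s) {
    cfg <- sim_config(group_sizes = c(control = 25, mci = 15, ad = 10),
                      n_trials_full = 12, short_len_range = c(6L, 11L),
                      seed = 2000 + s)
    co_s <- simulate_cohort(cfg)
    f <- fit_glmm(co_s, compute_vcov = FALSE)
    ci <- bootstrap_sigma_ci(f, B = 99, seed = 3000 + s)
    ci$lower <= 1.374 && 1.374 <= ci$upper
  })
  expect_gte(sum(cover), 0.9 * 25)
})

test_that("average-participant predictions are logistic in the linear
           predictor with delta-method intervals", {
  co <- cohort_202()
  fit <- fit_glmm(co)
  base <- predict_average(fit, tibble::tibble(group = "control",
                                              n_prev_success = 0,
                                              n_prev_fail = 0))
  expect_equal(base$prob, plogis(unname(fit$beta["(Intercept)"])))
  expect_error(predict_average(fit, tibble::tibble(group = "control")),
               "missing covariates")

  # with a negative error-run slope on the correct-coded response the
  # predicted error probability grows with error-run length
  expect_lt(unname(fit$beta["n_prev_fail"]), 0)
  pr <- predict_average(fit, tibble::tibble(group = "ad",
                                            n_prev_success = 0,
                                            n_prev_fail = 0:6))
  expect_true(all(diff(1 - pr$prob) > 0))

  # delta-method interval matches Monte-Carlo propagation from the
  # coefficient covariance
  nd <- tibble::tibble(group = "mci", n_prev_success = 2, n_prev_fail = 0)
  got <- predict_average(fit, nd)
  X <- stats::model.matrix(fit$fixed, data = transform(
    nd, group = factor(group, levels = c("control", "mci", "ad"))))
  set.seed(115)
  vb <- fit$vcov[seq_along(fit$beta), seq_along(fit$beta)]
  draws <- rmvn(10000, fit$beta[colnames(X)], vb)
  mc <- plogis(drop(draws %*% t(X)))
  expect_lt(abs(got$lower - quantile(mc, 0.025)), 0.005)
  expect_lt(abs(got$upper - quantile(mc, 0.975)), 0.005)
})

test_that("tidy and glance expose the fit in broom conventions", {
  fit <- fit_glmm(cohort_202())
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_true("sd__participant" %in% td$term)
  expect_equal(td$estimate[td$term == "sd__participant"], fit$sigma_u)
  gl <- glance(fit)
  expect_equal(gl$nobs, fit$n_obs)
  expect_true(gl$converged)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
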