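# Shared fixtures and independent oracles, all built in code.

small_config <- function(seed = 11, ...) {
  sim_config(group_sizes = c(control = 10, mci = 8, ad = 6), seed = seed,
             ...)
}

# one medium cohort reused across files (built once per test run)
cohort_202 <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- simulate_cohort(sim_config(seed = 5))
    memo
  }
})

# Brute-force marginal log-likelihood oracle: per-participant trapezoidal
# integration of the Bernoulli likelihood against the Normal(0, sigma^2)
# random-intercept density on a fine grid. Independent of the quadrature
# code path.
grid_loglik <- function(beta, sigma, X, y, ids, n_grid = 2001, width = 10) {
  eta0 <- drop(X %*% beta)
  u <- seq(-width * sigma, width * sigma, length.out = n_grid)
  du <- u[2] - u[1]
  phi <- dnorm(u, 0, sigma)
  ll <- 0
  for (pid in unique(ids)) {
    rows <- which(ids == pid)
    f <- vapply(u, function(ui) {
      p <- plogis(eta0[rows] + ui)
      prod(ifelse(y[rows] == 1, p, 1 - p))
    }, numeric(1))
    v <- f * phi
    ll <- ll + log(sum((v[-1] + v[-n_grid]) / 2) * du)
  }
  ll
}

# fixed tiny dataset for the quadrature oracle: 5 participants x 4 trials
tiny_glmm_data <- function() {
  tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:5), each = 4),
    group = rep(c("control", "control", "mci", "ad", "ad"), each = 4),
    trial_index = rep(1:4, 5),
    outcome = c("correct", "correct", "error_corrected", "correct",
                "error_uncorrected", "correct", "correct", "correct",
                "correct", "error_corrected", "error_corrected", "correct",
                "error_uncorrected", "error_uncorrected", "correct",
                "error_corrected", "correct", "error_corrected", "correct",
                "correct"),
    n_prev_success = c(0, 1, 2, 0, 0, 0, 1, 2, 0, 1, 0, 0, 0, 0, 0, 1, 0, 1,
                       0, 1),
    n_prev_fail = c(0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 1, 2, 0, 1, 2, 0, 0, 0, 1,
                    0)
  )
}

# draws from MVN(mu, Sigma) via Cholesky (test-local, avoids extra deps)
rmvn <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  matrix(rnorm(n * length(mu)), n) %*% L + rep(mu, each = n)
}

# reconstructed previous-outcome cell counts from the published summary
# table (errors, printed proportion) -> (errors, total)
published_table2_cells <- function() {
  tibble::tribble(
    ~group, ~condition, ~errors, ~proportion,
    "control", "prev_error_uncorrected", 78L, 0.595,
    "control", "prev_error_corrected", 362L, 0.574,
    "control", "prev_correct", 319L, 0.234,
    "mci", "prev_error_uncorrected", 141L, 0.758,
    "mci", "prev_error_corrected", 374L, 0.625,
    "mci", "prev_correct", 260L, 0.389,
    "ad", "prev_error_uncorrected", 123L, 0.815,
    "ad", "prev_error_corrected", 262L, 0.686,
    "ad", "prev_correct", 140L, 0.335
  )
}
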