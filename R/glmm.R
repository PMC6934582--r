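#' Fit a Bernoulli random-intercept multilevel model
#'
#' Maximum-likelihood fit of a logistic model with one Gaussian random
#' intercept per participant: the per-trial response (by default, whether
#' the trial was *correct*) follows
#' `logit(p_ij) = x_ij' beta + u_i`, `u_i ~ Normal(0, sigma_u^2)`. The
#' marginal likelihood integrates `u_i` out per participant by adaptive
#' Gauss-Hermite quadrature (grid centred and scaled at each cluster's
#' posterior mode); optimisation is box-constrained quasi-Newton starting
#' at the plain logistic-regression solution with `sigma_u = 1`, and
#' standard errors come from the inverse observed information.
#'
#' Response coding: `response_coding = "correct"` (default, matching the
#' generator's reference outcome) codes the response 1 for a correct trial;
#' `"error"` codes 1 for an inhibitory error. The two codings give identical
#' likelihoods with all coefficients negated.
#'
#' If the `sigma_u` estimate collapses to the boundary at zero the model
#' degenerates to plain logistic regression; the fit is then refreshed from
#' the exact `stats::glm()` solution and flagged (`boundary = TRUE`).
#'
#' @param trials Trial-level tibble containing `participant_id`, `outcome`
#'   (or a 0/1 `y` column) plus every covariate named in `fixed`. Excluded
#'   trials are dropped.
#' @param fixed One-sided formula for the fixed effects, e.g.
#'   `~ group + n_prev_success + n_prev_fail` or `~ group + prev_outcome`.
#'   Group enters treatment-coded with control as reference.
#' @param response_coding `"correct"` (default) or `"error"`.
#' @param n_quad Number of adaptive Gauss-Hermite nodes (default 15).
#' @param random_intercept If `FALSE`, fits the plain logistic model (used
#'   for the random-effect deviance test).
#' @param start Optional named start values (`beta`, `sigma_u`) to warm-start
#'   the optimiser.
#' @param compute_vcov If `FALSE`, skips the observed-information inversion
#'   (used by the bootstrap, which only needs point estimates).
#' @param optim_control Overrides for the L-BFGS-B control list (the
#'   bootstrap relaxes `factr` for its warm-started refits).
#' @return An object of class `ast_glmm`: list with `beta`, `se_beta`,
#'   `sigma_u`, `se_sigma_u`, `loglik`, `vcov`, `converged`, `boundary`,
#'   `n_quad`, `fixed`, `response_coding`, `data` (model frame), `n_obs`,
#'   `n_participants`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(group_sizes = c(control = 20,
#'   mci = 10, ad = 10), seed = 2))
#' fit <- fit_glmm(cohort, ~ group + n_prev_success + n_prev_fail)
#' tidy(fit)
fit_glmm <- function(trials, fixed = ~ group + n_prev_success + n_prev_fail,
                     response_coding = c("correct", "error"), n_quad = 15,
                     random_intercept = TRUE, start = NULL,
                     compute_vcov = TRUE, optim_control = list()) {
  response_coding <- match.arg(response_coding)
  mf <- prepare_glmm_frame(trials, fixed, response_coding)
  X <- mf$X; y <- mf$y
  if (qr(X)$rank < ncol(X)) abort("fixed-effect design matrix is rank deficient")
  if (mf$n_participants < 2) abort("need >= 2 participants")

  glm_boundary_fit <- function(converged = TRUE) {
    glm0 <- glm.fit(X, y, family = binomial())
    beta0 <- coef(glm0)
    mu0 <- plogis(drop(X %*% beta0))
    ll_glm <- sum(y * log(mu0) + (1 - y) * log(1 - mu0))
    vc <- chol2inv(chol(crossprod(X * sqrt(glm0$weights))))
    new_ast_glmm(beta = beta0, se_beta = sqrt(diag(vc)),
                 sigma_u = 0, se_sigma_u = NA_real_,
                 loglik = ll_glm, vcov = vc, converged = converged,
                 boundary = TRUE, n_quad = n_quad, fixed = fixed,
                 response_coding = response_coding, mf = mf)
  }
  if (!random_intercept) return(glm_boundary_fit())

  gh <- pracma::gaussHermite(n_quad)
  if (is.null(start)) {
    beta0 <- coef(glm.fit(X, y, family = binomial()))
    par0 <- c(beta0, 1)
  } else {
    par0 <- c(start$beta, start$sigma_u)
  }
  p <- ncol(X)
  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e6), optim_control)
  opt <- glmm_optimize(X, y, mf$start_idx, mf$len, gh, par0, ctrl)
  est <- opt$par
  converged <- opt$converged
  # sigma at the boundary: the ML solution is the plain logistic fit
  if (opt$boundary) return(glm_boundary_fit(converged))
  if (compute_vcov) {
    nll <- function(par) glmm_nll_cpp(par, X, y, mf$start_idx, mf$len,
                                      gh$x, gh$w)
    ngr <- function(par) glmm_nll_grad_cpp(par, X, y, mf$start_idx, mf$len,
                                           gh$x, gh$w)
    H <- optimHess(est, nll, ngr)
    vc <- tryCatch(chol2inv(chol(H)), error = function(e) {
      warn("observed information not positive definite; SEs from pseudoinverse")
      MASS_ginv(H)
    })
    se <- sqrt(pmax(diag(vc), 0))
  } else {
    vc <- matrix(NA_real_, p + 1, p + 1)
    se <- rep(NA_real_, p + 1)
  }
  if (!converged) warn("optimiser did not report convergence")
  new_ast_glmm(beta = setNames(est[1:p], colnames(X)), se_beta = se[1:p],
               sigma_u = unname(est[p + 1]), se_sigma_u = unname(se[p + 1]),
               loglik = -opt$value, vcov = vc, converged = converged,
               boundary = FALSE, n_quad = n_quad, fixed = fixed,
               response_coding = response_coding, mf = mf)
}


# Optimiser core shared by fit_glmm and the bootstrap fast path: maximises
# the adaptive-quadrature marginal likelihood from `par0`.
glmm_optimize <- function(X, y, start_idx, len, gh, par0, ctrl) {
  cache <- new.env(parent = emptyenv())
  eval_vg <- function(par) {
    if (!identical(cache$par, par)) {
      cache$vg <- glmm_nll_vg_cpp(par, X, y, start_idx, len, gh$x, gh$w)
      cache$par <- par
    }
    cache$vg
  }
  p <- ncol(X)
  opt <- optim(par0, function(par) eval_vg(par)$value,
               gr = function(par) eval_vg(par)$grad, method = "L-BFGS-B",
               lower = c(rep(-Inf, p), 1e-6), control = ctrl)
  conv <- opt$convergence == 0 ||
    max(abs(eval_vg(opt$par)$grad)) < 0.05
  list(par = opt$par, sigma_u = unname(opt$par[p + 1]),
       value = opt$value, converged = conv,
       boundary = opt$par[p + 1] < 0.01)
}

# Moore-Penrose pseudoinverse via SVD (fallback for a singular Hessian)
MASS_ginv <- function(H, tol = 1e-10) {
  s <- svd(H)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

prepare_glmm_frame <- function(trials, fixed, response_coding) {
  dat <- as_tibble(trials)
  if ("outcome" %in% names(dat)) {
    dat <- dat %>% filter(is.na(.data$outcome) | .data$outcome != "excluded")
  } else if (!"y" %in% names(dat)) {
    abort("`trials` must carry an `outcome` or a 0/1 `y` column")
  }
  if ("group" %in% names(dat)) {
    dat$group <- droplevels(
      factor(as.character(dat$group), levels = group_levels()))
  }
  if ("prev_outcome" %in% all.vars(fixed) &&
      !"prev_outcome" %in% names(dat)) {
    dat <- dat %>%
      arrange(.data$participant_id, .data$trial_index) %>%
      group_by(.data$participant_id) %>%
      mutate(prev_outcome = lag(as.character(.data$outcome))) %>%
      ungroup() %>%
      filter(!is.na(.data$prev_outcome)) %>%
      mutate(prev_outcome = factor(.data$prev_outcome,
                                   levels = c("correct", "error_corrected",
                                              "error_uncorrected")))
  }
  dat <- dat %>% arrange(.data$participant_id)
  X <- model.matrix(fixed, data = dat)
  if ("y" %in% names(dat)) {
    # `y` = 1 for a correct trial (the generator's reference coding)
    y <- as.numeric(dat$y)
    if (response_coding == "error") y <- 1 - y
  } else {
    correct <- dat$outcome == "correct"
    y <- if (response_coding == "correct") as.numeric(correct) else
      as.numeric(!correct)
  }
  ids <- dat$participant_id
  r <- rle(as.character(ids))
  len <- r$lengths
  start_idx <- cumsum(c(0L, head(len, -1)))
  list(X = X, y = y, data = dat, start_idx = as.integer(start_idx),
       len = as.integer(len), n_participants = length(len))
}

new_ast_glmm <- function(beta, se_beta, sigma_u, se_sigma_u, loglik, vcov,
                         converged, boundary, n_quad, fixed,
                         response_coding, mf) {
  structure(
    list(beta = beta, se_beta = setNames(se_beta, names(beta)),
         sigma_u = sigma_u, se_sigma_u = se_sigma_u, loglik = loglik,
         vcov = vcov, converged = converged, boundary = boundary,
         n_quad = n_quad, fixed = fixed, response_coding = response_coding,
         data = mf$data, X = mf$X, y = mf$y, start_idx = mf$start_idx,
         len = mf$len, n_obs = length(mf$y),
         n_participants = mf$n_participants),
    class = "ast_glmm"
  )
}

#' @export
print.ast_glmm <- function(x, ...) {
  cat("Bernoulli random-intercept model (adaptive Gauss-Hermite, ",
      x$n_quad, " nodes)\n", sep = "")
  cat("response = 1 for a", x$response_coding, "trial;",
      x$n_obs, "trials,", x$n_participants, "participants\n")
  print(tidy(x), n = Inf)
  cat(sprintf("sigma_u = %.3f, logLik = %.3f%s\n", x$sigma_u, x$loglik,
              if (x$boundary) " (sigma at boundary)" else ""))
  invisible(x)
}

#' Tidy method for antisaccade multilevel fits
#'
#' @param x An `ast_glmm` fit.
#' @param ... Unused.
#' @return Tibble with one row per fixed effect plus the random-intercept
#'   SD: `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.ast_glmm <- function(x, ...) {
  fx <- tibble(term = names(x$beta), estimate = unname(x$beta),
               std.error = unname(x$se_beta)) %>%
    mutate(statistic = .data$estimate / .data$std.error,
           p.value = 2 * pnorm(-abs(.data$statistic)))
  bind_rows(fx, tibble(term = "sd__participant", estimate = x$sigma_u,
                       std.error = x$se_sigma_u, statistic = NA_real_,
                       p.value = NA_real_))
}

#' Glance method for antisaccade multilevel fits
#'
#' @inheritParams tidy.ast_glmm
#' @return One-row tibble: `logLik`, `AIC`, `BIC`, `sigma_u`, `nobs`,
#'   `n_participants`, `converged`, `boundary`.
#' @export
glance.ast_glmm <- function(x, ...) {
  k <- length(x$beta) + as.numeric(!x$boundary)
  tibble(logLik = x$loglik, AIC = -2 * x$loglik + 2 * k,
         BIC = -2 * x$loglik + log(x$n_obs) * k, sigma_u = x$sigma_u,
         nobs = x$n_obs, n_participants = x$n_participants,
         converged = x$converged, boundary = x$boundary)
}

#' Likelihood-ratio (deviance) test of nested multilevel models
#'
#' `statistic = 2 (logLik_full - logLik_reduced)` referred to a chi-squared
#' distribution with df equal to the parameter-count difference. Models must
#' be fitted to the same trials; the reduced fixed-effect terms must be a
#' subset of the full ones (or the models differ only in the random
#' intercept). When the test concerns the random-effect SD the null lies on
#' the boundary of the parameter space, which makes the chi-squared
#' reference conservative; a message notes this.
#'
#' @param fit_full,fit_reduced `ast_glmm` fits.
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
deviance_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "ast_glmm"), inherits(fit_reduced, "ast_glmm"))
  if (fit_full$n_obs != fit_reduced$n_obs) {
    abort("models were not fitted to the same data")
  }
  full_terms <- colnames(fit_full$X)
  red_terms <- colnames(fit_reduced$X)
  if (!all(red_terms %in% full_terms)) {
    abort("reduced model is not nested in the full model")
  }
  k_full <- length(fit_full$beta) + as.numeric(!fit_full$boundary)
  k_red <- length(fit_reduced$beta) + as.numeric(!fit_reduced$boundary)
  df <- k_full - k_red
  if (df < 0) abort("reduced model has more parameters than the full model")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  if (fit_reduced$boundary && !fit_full$boundary &&
      setequal(red_terms, full_terms)) {
    inform("random-effect test: null on the boundary; chi-squared reference is conservative")
  }
  p <- if (df == 0) as.numeric(stat <= 1e-8) else pchisq(stat, df,
                                                         lower.tail = FALSE)
  tibble(statistic = stat, df = df, p = p)
}

#' Parametric-bootstrap confidence interval for the random-intercept SD
#'
#' Simulates `B` datasets from the fitted model — redrawing random
#' intercepts and regenerating each participant's outcome sequence (the
#' run-length covariates are dynamic, so sequences are re-rolled, not
#' resampled) — refits each, and returns percentile bounds of the
#' `sigma_u` estimates. Refit failures are dropped with a count; more than
#' 10\% failures is an error.
#'
#' @param fit A converged `ast_glmm` fit of the run-length model.
#' @param B Number of bootstrap replicates (default 500).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap stream.
#' @return One-row tibble: `sigma_u`, `lower`, `upper`, `level`, `B_used`.
#' @export
bootstrap_sigma_ci <- function(fit, B = 500, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "ast_glmm"))
  if (B < 1) abort("`B` must be a positive integer")
  if (!fit$converged) abort("base fit did not converge")
  if ("prev_outcome" %in% all.vars(fit$fixed)) {
    abort("parametric bootstrap is defined for the run-length model (previous-outcome covariates cannot be re-rolled without the correction process)")
  }
  co <- glmm_coef_list(fit)
  skeleton <- fit$data %>% select("participant_id", "group", "trial_index")
  gh <- pracma::gaussHermite(fit$n_quad)
  par0 <- c(fit$beta, fit$sigma_u)
  p <- length(fit$beta)
  run_cols <- c("n_prev_success", "n_prev_fail")
  direct <- all(run_cols %in% colnames(fit$X))
  sims <- with_stream(seed, {
    purrr::map_dbl(seq_len(B), function(b) {
      dat <- resimulate_outcomes(skeleton, co$intercepts, co$slope_success,
                                 co$slope_error, fit$sigma_u,
                                 reference_outcome = fit$response_coding)
      if (direct) {
        # rows of `dat` align with the parent design (same participants in
        # the same sorted order); only the run-length columns and the
        # response change between bootstrap replicates
        X2 <- fit$X
        X2[, "n_prev_success"] <- dat$n_prev_success
        X2[, "n_prev_fail"] <- dat$n_prev_fail
        y2 <- if (fit$response_coding == "correct") {
          as.numeric(!dat$error)
        } else as.numeric(dat$error)
        opt <- tryCatch(
          glmm_optimize(X2, y2, fit$start_idx, fit$len, gh, par0,
                        list(maxit = 500, factr = 1e8)),
          error = function(e) NULL)
        if (is.null(opt) || !opt$converged) NA_real_ else opt$sigma_u
      } else {
        dat$y <- as.numeric(!dat$error)   # 1 = correct; fit_glmm recodes
        f <- tryCatch(
          fit_glmm(dat, fit$fixed, response_coding = fit$response_coding,
                   n_quad = fit$n_quad,
                   start = list(beta = fit$beta, sigma_u = fit$sigma_u),
                   compute_vcov = FALSE,
                   optim_control = list(factr = 1e8)),
          error = function(e) NULL)
        if (is.null(f) || !f$converged) NA_real_ else f$sigma_u
      }
    })
  })
  ok <- sims[!is.na(sims)]
  if (length(ok) < 0.9 * B) {
    abort(sprintf("too many bootstrap refit failures (%d of %d)",
                  B - length(ok), B))
  }
  a <- (1 - level) / 2
  tibble(sigma_u = fit$sigma_u,
         lower = unname(quantile(ok, a)),
         upper = unname(quantile(ok, 1 - a)),
         level = level, B_used = length(ok))
}

# Map a fitted run-length model's coefficients back onto generator terms
# (control intercept + group offsets + the two run-length slopes).
glmm_coef_list <- function(fit) {
  b <- fit$beta
  pick <- function(nm) if (nm %in% names(b)) unname(b[nm]) else 0
  list(
    intercepts = c(control = pick("(Intercept)"),
                   mci = pick("groupmci"), ad = pick("groupad")),
    slope_success = pick("n_prev_success"),
    slope_error = pick("n_prev_fail")
  )
}

#' Predicted probability for an average participant
#'
#' Evaluates `plogis(x' beta)` at `u = 0` (an average participant) for each
#' row of `newdata`, with a delta-method confidence interval propagated from
#' the coefficient covariance on the linear-predictor scale.
#'
#' @param fit An `ast_glmm` fit.
#' @param newdata Tibble of covariate values covering every term of the
#'   fit's fixed formula.
#' @param level Confidence level (default 0.95).
#' @return `newdata` with `prob`, `lower`, `upper` columns appended
#'   (probability of the fit's coded response).
#' @export
predict_average <- function(fit, newdata, level = 0.95) {
  stopifnot(inherits(fit, "ast_glmm"))
  miss <- setdiff(all.vars(fit$fixed), names(newdata))
  if (length(miss) > 0) {
    abort(paste("missing covariates:", paste(miss, collapse = ", ")))
  }
  nd <- as_tibble(newdata)
  if ("group" %in% names(nd)) {
    nd$group <- factor(as.character(nd$group), levels = group_levels())
  }
  X <- model.matrix(fit$fixed, data = nd)
  if (!all(colnames(X) %in% names(fit$beta))) {
    abort("covariate levels outside the fitted design")
  }
  eta <- drop(X %*% fit$beta[colnames(X)])
  vb <- fit$vcov[seq_along(fit$beta), seq_along(fit$beta), drop = FALSE]
  se_eta <- sqrt(pmax(rowSums((X %*% vb) * X), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  nd$prob <- unname(plogis(eta))
  nd$lower <- unname(plogis(eta - zq * se_eta))
  nd$upper <- unname(plogis(eta + zq * se_eta))
  nd
}

#' Plot average-participant predicted probabilities against run length
#'
#' @param fit An `ast_glmm` fit of the run-length model.
#' @param max_len Largest preceding run length to display (default 6).
#' @param as `"error"` (default) or `"correct"`: probability scale to show.
#' @return A ggplot object: predicted probability (ribbon = 95\% CI) versus
#'   signed run length (negative = preceding error runs, positive =
#'   preceding correct runs) by group.
#' @export
plot_predicted_probability <- function(fit, max_len = 6,
                                       as = c("error", "correct")) {
  as <- match.arg(as)
  grid <- bind_rows(
    tidyr::crossing(group = group_levels(),
                    n_prev_success = 0:max_len, n_prev_fail = 0) %>%
      mutate(run = .data$n_prev_success),
    tidyr::crossing(group = group_levels(), n_prev_success = 0,
                    n_prev_fail = 1:max_len) %>%
      mutate(run = -.data$n_prev_fail)
  )
  pr <- predict_average(fit, grid)
  flip <- (as == "error") == (fit$response_coding == "correct")
  if (flip) {
    pr <- pr %>% mutate(prob = 1 - .data$prob,
                        lo = 1 - .data$upper, hi = 1 - .data$lower) %>%
      mutate(lower = .data$lo, upper = .data$hi)
  }
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$run, y = .data$prob,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "preceding consecutive errors (-) / successes (+)",
                  y = paste("P(", as, ") for an average participant"),
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ast_glmm <- function(object, ...) {
  plot_predicted_probability(object, ...)
}
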