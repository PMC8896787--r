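ri_dm3_session <- function(n = 2500, seed = 101,
                           truth = dm_params("DM3",
                             sigma = c(14, 10, 7),
                             beta0 = 0.15, beta1 = 0.25, beta2 = 0.6,
                             lapse = 0.05
                           )) {
  simulate_session(session_spec(
    n_trials = n, env_id = "constant", truth = truth, seed = seed
  ))
}

test_that("the likelihood engine matches scalar computations", {
  p1 <- dm_params("DM1", sigma = 1e9) # near-chance probabilities
  tr <- tibble::tibble(
    theta_l = 60, theta_r = 30, c_l = 1, c_r = 1, choice = "left"
  )
  expect_equal(negative_log_likelihood(tr, p1), log(2), tolerance = 1e-6)
  # additivity under duplication
  p3 <- dm_params("DM3", sigma = c(10, 8, 6), beta2 = 0.3, lapse = 0.04)
  tr20 <- ri_dm3_session(n = 20, seed = 7)
  nll1 <- negative_log_likelihood(tr20, p3)
  expect_equal(negative_log_likelihood(dplyr::bind_rows(tr20, tr20), p3), 2 * nll1)
  # per-trial scalar oracle
  probs <- dm_choice_probability(tr20, p3)$p_left
  oracle <- -sum(log(ifelse(tr20$choice == "left", probs, 1 - probs)))
  expect_equal(nll1, oracle, tolerance = 1e-12)
  expect_error(negative_log_likelihood(tr20[0, ], p3), "empty")
  expect_error(
    negative_log_likelihood(dplyr::select(tr20, -"choice"), p3),
    "choice"
  )
})

test_that("descriptive model fits recover generating parameters and nest properly", {
  tr <- ri_dm3_session(n = 4000, seed = 55)
  f1 <- fit_dm(tr, "DM1", starts = 8, seed = 1)
  f2 <- fit_dm(tr, "DM2", starts = 8, seed = 2)
  f3 <- fit_dm(tr, "DM3", starts = 8, seed = 3)
  # nesting: each model is a restriction of the next
  expect_gte(f3$logLik, f2$logLik - 1e-6)
  expect_gte(f2$logLik, f1$logLik - 1e-6)
  # fitted DM3 close to the generating parameters
  est <- tidy(f3)
  sig <- est$estimate[grepl("^sigma", est$term)]
  expect_equal(sort(sig, decreasing = TRUE), c(14, 10, 7), tolerance = 0.25)
  expect_equal(est$estimate[est$term == "beta2"], 0.6, tolerance = 0.35)
  # local optimality: fitted parameters beat perturbations of themselves
  nll_fit <- -f3$logLik
  perturbed <- dm_params("DM3",
    sigma = sig * 1.15,
    beta0 = est$estimate[est$term == "beta0"] + 0.1,
    beta1 = est$estimate[est$term == "beta1"],
    beta2 = est$estimate[est$term == "beta2"],
    lapse = min(est$estimate[est$term == "lapse"] + 0.05, 1)
  )
  expect_lt(nll_fit, negative_log_likelihood(tr, perturbed))
})

test_that("information criteria and comparison tables are arithmetically exact", {
  tr <- ri_dm3_session(n = 800, seed = 77)
  f1 <- fit_dm(tr, "DM1", starts = 4, seed = 1)
  f3 <- fit_dm(tr, "DM3", starts = 4, seed = 2)
  expect_equal(f1$AIC, 2 * f1$n_params - 2 * f1$logLik, tolerance = 1e-10)
  expect_equal(f3$BIC, f3$n_params * log(f3$n_trials) - 2 * f3$logLik,
    tolerance = 1e-10
  )
  cmp <- compare_fits(f1, f3)
  expect_equal(cmp$dAIC[1], 0)
  expect_equal(sort(cmp$model), sort(c("DM1", "DM3")))
  expect_equal(max(cmp$dAIC), abs(f1$AIC - f3$AIC), tolerance = 1e-10)
  # identical fits tie at zero
  cmp2 <- compare_fits(f3, f3)
  expect_equal(cmp2$dAIC, c(0, 0))
  other <- ri_dm3_session(n = 800, seed = 78)
  f_other <- fit_dm(other, "DM1", starts = 2, seed = 1)
  expect_error(compare_fits(f1, f_other), "same trial table")
})

test_that("observer fit variants run and respect nesting", {
  obs_truth <- ri_uniform_obs(k_max = 10, sigma_late = 10, beta2 = 0.4)
  tr <- simulate_session(session_spec(
    n_trials = 1500, env_id = "constant",
    truth = obs_truth, seed = 91
  ))
  fc <- fit_observer(tr, ri_prior, "g-const", starts = 4, seed = 1, maxit = 250)
  ff <- fit_observer(tr, ri_prior, "g-free", starts = 4, seed = 2, maxit = 250)
  expect_gte(ff$logLik, fc$logLik - 0.5) # g-const nested in g-free
  expect_equal(ff$n_params, 10L)
  expect_equal(fc$n_params, 7L)
  expect_s3_class(glance(ff), "tbl_df")
})

test_that("the endogenous variant derives its gain from the inner optimizer", {
  obs_truth <- ri_uniform_obs(k_max = 8, sigma_late = 12)
  tr <- simulate_session(session_spec(
    n_trials = 400, env_id = "increasing",
    truth = obs_truth, seed = 93
  ))
  fe <- fit_observer(tr, ri_prior, "g-endog",
    starts = 1, seed = 4,
    inner_starts = 2, inner_maxit = 60, maxit = 25
  )
  expect_equal(fe$n_params, 7L) # same complexity as DM3
  expect_true(is.finite(fe$logLik))
  expect_s3_class(fe$params$gain, "ri_gain")
})

test_that("covariate modulation recovers nulls and signed effects", {
  base <- observer_params(
    resource_gain(c(0, 0, 0)), contrast_response(10, 2, 0.5),
    sigma_late = 20
  )
  spec <- session_spec(n_trials = 20000, env_id = "constant", truth = base, seed = 301)
  tr <- generate_trials(spec)
  tr$covariate <- rep(c("low", "high"), length.out = nrow(tr))
  # null effect: both factors near 1
  p <- choice_probability(tr, base, ri_prior)$p_left
  tr$choice <- withr::with_seed(11, ifelse(runif(nrow(tr)) < p, "left", "right"))
  f0 <- fit_covariate_modulation(tr, base, ri_prior, starts = 4, seed = 5)
  expect_true(all(abs(f0$estimates$s_sens - 1) < 0.25))
  expect_true(all(abs(f0$estimates$s_late - 1) < 0.4))

  # generative drop in late precision for the high level, recovered in sign
  hi <- tr$covariate == "high"
  obs_lo <- base
  obs_hi <- modulated_observer(base, s_late = 0.4)
  p2 <- p
  p2[hi] <- choice_probability(tr[hi, ], obs_hi, ri_prior)$p_left
  tr2 <- tr
  tr2$choice <- withr::with_seed(12, ifelse(runif(nrow(tr)) < p2, "left", "right"))
  f1 <- fit_covariate_modulation(tr2, base, ri_prior, starts = 4, seed = 6)
  est <- f1$estimates
  expect_lt(est$s_late[est$level == "high"], est$s_late[est$level == "low"])
  expect_error(
    fit_covariate_modulation(dplyr::mutate(tr, covariate = "low"), base, ri_prior),
    "two populated levels"
  )
})

test_that("bootstrap confidence intervals behave", {
  expect_warning(
    bootstrap_ci(c(1, 1, 1, 2), function(x) {
      if (length(unique(x)) == 1) NA_real_ else mean(x)
    }, reps = 200, seed = 2),
    regexp = "degenerate"
  )
  ci <- bootstrap_ci(rep(3, 50), mean, reps = 200, seed = 1)
  expect_equal(ci$lower, 3)
  expect_equal(ci$upper, 3)
  x <- withr::with_seed(7, rnorm(10000))
  ci2 <- bootstrap_ci(x, mean, reps = 300, seed = 3)
  expect_lt(ci2$lower, 0)
  expect_gt(ci2$upper, 0)
  expect_identical(ci2, bootstrap_ci(x, mean, reps = 300, seed = 3))
  expect_error(bootstrap_ci(x, mean, reps = 10), "reps")
})
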