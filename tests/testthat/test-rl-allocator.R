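test_that("confidence is chance for identical stimuli and certainty without noise", {
  obs <- ri_uniform_obs(k_max = 12, sigma_late = 6)
  same <- tibble::tibble(theta_l = 40, theta_r = 40, c_l = 1, c_r = 1)
  expect_equal(confidence(same, obs, ri_prior)$confidence, 0.5)
  sharp <- ri_uniform_obs(k_max = 5e4, sigma_late = 0)
  tr <- tibble::tibble(theta_l = 70, theta_r = 30, c_l = 1, c_r = 1)
  expect_gt(confidence(tr, sharp, ri_prior)$confidence, 0.999)
  # always at least chance
  cc <- confidence(ri_trial_grid(), obs, ri_prior)$confidence
  expect_true(all(cc >= 0.5 & cc <= 1))
})

test_that("confidence tracks simulated conditional correctness", {
  obs <- ri_uniform_obs(k_max = 15, sigma_late = 6)
  tr <- tibble::tibble(theta_l = 64, theta_r = 30, c_l = 0.6, c_r = 0.6)
  cf <- confidence(tr, obs, ri_prior)$confidence
  n <- 3e4
  sim <- simulate_choice(tr[rep(1, n), ], obs, ri_prior, seed = 4)
  # P(chosen side correct) equals max(p, 1 - p) of the choice distribution
  emp <- max(mean(sim$choice == "left"), 1 - mean(sim$choice == "left"))
  expect_lt(abs(cf - emp), 0.02 + 3 * sqrt(0.25 / n))
})

test_that("the divisive learning rate behaves across its range", {
  p <- rl_params(alpha_plus = 0, alpha_minus = 0.2)
  expect_equal(learning_rate(0.7, +1, p), 1)
  expect_equal(learning_rate(0.8, -1, p), 0.8 / (0.8 + 0.2))
  expect_lt(learning_rate(1, -1, rl_params(alpha_minus = 1e8)), 1e-7)
})

test_that("prediction errors follow the kernel in both forms", {
  bel <- reward_belief(value = 3)
  p_sc <- rl_params(k_tilde = 2)
  p_lit <- rl_params(k_tilde = 2, form = "literal")
  d_sc <- prediction_error_vector(8, 40, bel, p_sc)
  d_lit <- prediction_error_vector(8, 40, bel, p_lit)
  i <- which(bel$theta == 40)
  expect_equal(d_sc[i], 8 - 3)
  expect_equal(d_lit[i], 8 - 3)
  # independent kernel evaluation
  psi <- bel$theta * pi / 90
  kern <- exp(2 * (cos(psi[i] - psi) - 1))
  expect_equal(d_sc, (8 - 3) * kern, tolerance = 1e-12)
  expect_equal(d_lit, 8 - 3 * kern, tolerance = 1e-12)
  # kernel collapse at large concentration
  d_far <- prediction_error_vector(8, 40, bel, rl_params(k_tilde = 1e5, form = "literal"))
  expect_equal(d_far[i], 5)
  expect_equal(d_far[bel$theta == 130], 8, tolerance = 1e-6)
  d_far_sc <- prediction_error_vector(8, 40, bel, rl_params(k_tilde = 1e5))
  expect_equal(d_far_sc[bel$theta == 130], 0, tolerance = 1e-6)
})

test_that("updates preserve normalization and nonnegativity", {
  bel <- reward_belief(value = 5)
  p <- rl_params(alpha_plus = 1, alpha_minus = 1, k_tilde = 2)
  for (i in 1:20) {
    rwd <- c(0, 8, 3, 0, 5)[(i %% 5) + 1]
    out <- update_and_normalize(bel, rwd, (i * 17) %% 180, 0.8, p)
    bel <- out$belief
    expect_true(all(bel$value >= 0))
    g_norm <- bel$value / sum(bel$value)
    expect_equal(sum(g_norm), 1, tolerance = 1e-12)
  }
  # frozen learning leaves the belief unchanged
  frozen <- rl_params(alpha_plus = 1e12, alpha_minus = 1e12)
  before <- reward_belief(value = 5)
  after <- update_and_normalize(before, 8, 40, 0.9, frozen)$belief
  expect_equal(after$value, before$value, tolerance = 1e-9)
})

test_that("closed-loop sessions are reproducible and reward-shaped", {
  obs <- ri_uniform_obs(k_max = 6, sigma_late = 10)
  spec <- session_spec(n_trials = 700, env_id = "increasing", seed = 14)
  tr <- generate_trials(spec)
  run1 <- run_rl_session(tr, obs, ri_prior, seed = 2)
  run2 <- run_rl_session(tr, obs, ri_prior, seed = 2)
  expect_identical(run1$g_trace, run2$g_trace)
  expect_true(all(abs(rowSums(run1$g_trace) - 1) < 1e-12))

  # increasing environment ends with more vertical allocation than constant
  spec_c <- session_spec(n_trials = 700, env_id = "constant", seed = 14)
  run_c <- run_rl_session(generate_trials(spec_c), obs, ri_prior, seed = 2)
  vb <- which(verticality(run1$grid) >= 70)
  hb <- which(verticality(run1$grid) <= 20)
  g_inc <- mean_gain(run1, 300)$g
  g_con <- mean_gain(run_c, 300)$g
  expect_gt(mean(g_inc[vb]) / mean(g_inc[hb]), mean(g_con[vb]) / mean(g_con[hb]))
})

test_that("a mid-stream environment switch redirects the allocation", {
  obs <- ri_uniform_obs(k_max = 6, sigma_late = 10)
  half1 <- generate_trials(session_spec(n_trials = 500, env_id = "increasing", seed = 15))
  half2 <- generate_trials(session_spec(n_trials = 500, env_id = "decreasing", seed = 16))
  stream <- dplyr::bind_rows(half1, half2)
  stream$trial <- seq_len(nrow(stream))
  run <- run_rl_session(stream, obs, ri_prior, seed = 3)
  vb <- which(verticality(run$grid) >= 70)
  g_end_phase1 <- colMeans(run$g_trace[400:500, ])
  g_end_phase2 <- colMeans(run$g_trace[900:1000, ])
  # vertical allocation falls after switching to the decreasing mapping
  expect_lt(mean(g_end_phase2[vb]), mean(g_end_phase1[vb]))
})

test_that("faster learning from positive errors does not hurt asymptotic reward", {
  obs <- ri_uniform_obs(k_max = 6, sigma_late = 10)
  rew <- function(ap, am, seed) {
    tr <- generate_trials(session_spec(n_trials = 600, env_id = "increasing", seed = seed))
    run <- run_rl_session(tr, obs, ri_prior,
      params = rl_params(alpha_plus = ap, alpha_minus = am), seed = seed + 1
    )
    mean(run$trials$reward[301:600])
  }
  seeds <- c(51, 52, 53)
  asym <- mean(vapply(seeds, function(s) rew(20, 80, s), numeric(1)))
  sym <- mean(vapply(seeds, function(s) rew(50, 50, s), numeric(1)))
  expect_gte(asym, sym - 0.05)
})
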