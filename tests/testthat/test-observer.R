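test_that("measurement density is a normalized von Mises on the grid", {
  obs <- ri_uniform_obs()
  d <- measurement_density(44, 0.6, obs)
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  expect_equal(d$m[which.max(d$density)], 44) # mode at the stimulus

  # zero-concentration limit: uniform
  obs0 <- observer_params(resource_gain(c(0, 0, 0)),
    contrast_response(1e-9), sigma_late = 1
  )
  d0 <- measurement_density(45, 0.6, obs0)
  expect_true(all(abs(d0$density - 1 / 90) < 1e-10))

  # closed-form density ratio at two measurements, kappa = k(c) * g = 8
  obs8 <- observer_params(resource_gain(c(0, 0, 0)),
    contrast_response(16, q = 2, c50 = 1), sigma_late = 1
  ) # k(1) = 16/2 = 8
  d8 <- measurement_density(44, 1, obs8)
  ratio <- d8$density[d8$m == 44] / d8$density[d8$m == 90]
  dpsi <- (90 - 44) * pi / 90
  expect_equal(ratio, exp(8 * (1 - cos(dpsi))), tolerance = 1e-9)
})

test_that("BLS decoding follows the posterior mean", {
  flat <- orientation_prior(concentration = 0)
  obs <- ri_uniform_obs(k_max = 20)
  # flat prior, symmetric likelihood: estimate equals the measurement
  expect_equal(bls_estimate(c(30, 76, 120), obs, flat, 1), c(30, 76, 120),
    tolerance = 1e-6
  )
  # likelihood dominance: high concentration pins the estimate at m
  sharp <- ri_uniform_obs(k_max = 8000)
  expect_equal(bls_estimate(45, sharp, ri_prior, 1), 45, tolerance = 0.5)
  # horizontal-peaked prior attracts a moderate-precision estimate toward 0
  est <- bls_estimate(45, ri_uniform_obs(k_max = 10), ri_prior, 1)
  expect_lt(est, 45)
  expect_gt(est, 20)
  # agreement with an independently coded decode oracle
  kap <- k_of_contrast(obs$cr, 0.6) * obs$gain$g
  for (m in c(20, 44, 88)) {
    expect_equal(bls_estimate(m, obs, ri_prior, 0.6),
      ri_oracle_decode(m, kap, ri_prior),
      tolerance = 1e-8
    )
  }
})

test_that("estimator moments match a measurement-sampling Monte Carlo oracle", {
  obs <- ri_uniform_obs(k_max = 12, sigma_late = 5)
  mom <- estimator_moments(obs, ri_prior, c(30, 60), 0.6)
  n <- 2e5
  for (r in 1:2) {
    d <- measurement_density(mom$theta0[r], 0.6, obs)
    kap <- k_of_contrast(obs$cr, 0.6) * obs$gain$g
    # decode table computed independently, then sample measurements
    vhat_tab <- vapply(
      d$m, function(m) 90 - abs(90 - ri_oracle_decode(m, kap, ri_prior)),
      numeric(1)
    )
    set.seed(100 + r)
    idx <- sample.int(length(d$m), n, replace = TRUE, prob = d$density)
    v <- vhat_tab[idx]
    se_mean <- sd(v) / sqrt(n)
    expect_lt(abs(mean(v) - mom$mean[r]), 3 * se_mean + 1e-6)
    se_var <- sd((v - mean(v))^2) / sqrt(n)
    expect_lt(abs(var(v) - mom$var[r]), 3 * se_var + 1e-4)
  }
})

test_that("moment limits behave: noiseless variance, flat-prior symmetry", {
  sharp <- ri_uniform_obs(k_max = 5e4, sigma_late = 0)
  mom <- estimator_moments(sharp, ri_prior, c(30, 60, 80), 1)
  expect_true(all(mom$var < 1))
  flat <- orientation_prior(concentration = 0)
  obs <- ri_uniform_obs(k_max = 30)
  mom2 <- estimator_moments(obs, flat, c(30, 60), 1)
  # interior stimuli decode without systematic bias under a flat prior
  expect_equal(mom2$mean, verticality(c(30, 60)), tolerance = 1.5)
})

test_that("choice probability obeys symmetry, bias dominance and equivariance", {
  obs <- ri_uniform_obs()
  same <- tibble::tibble(theta_l = 50, theta_r = 50, c_l = 0.6, c_r = 0.6)
  expect_equal(choice_probability(same, obs, ri_prior)$p_left, 0.5)
  biased <- ri_uniform_obs(beta0 = 50)
  expect_gt(choice_probability(same, biased, ri_prior)$p_left, 0.999)

  # swapping sides maps p to 1 - p (beta0 = beta1 = 0; beta2 flips with c)
  obs2 <- ri_uniform_obs(k_max = 15, sigma_late = 6, beta2 = 0.4)
  tr <- ri_trial_grid()
  p <- choice_probability(tr, obs2, ri_prior)$p_left
  swapped <- dplyr::rename(tr,
    theta_l = theta_r, theta_r = theta_l, c_l = c_r, c_r = c_l
  )
  p_sw <- choice_probability(swapped, obs2, ri_prior)$p_left
  expect_equal(p_sw, 1 - p, tolerance = 1e-12)
})

test_that("choice probability matches its own Gaussian decision model", {
  obs <- ri_uniform_obs(k_max = 12, sigma_late = 6, beta0 = 0.2, beta2 = 0.3)
  tr <- tibble::tibble(theta_l = 70, theta_r = 40, c_l = 1, c_r = 0.3)
  p <- choice_probability(tr, obs, ri_prior)$p_left
  mom_l <- estimator_moments(obs, ri_prior, 70, 1)
  mom_r <- estimator_moments(obs, ri_prior, 40, 0.3)
  n <- 1e5
  set.seed(9)
  dv <- rnorm(n, mom_l$mean, sqrt(mom_l$var)) -
    rnorm(n, mom_r$mean, sqrt(mom_r$var)) +
    rnorm(n, 0, obs$sigma_late)
  scale <- sqrt(mom_l$var + mom_r$var + obs$sigma_late^2)
  p_mc <- mean(dv + (obs$beta0 + obs$beta2 * (1 - 0.3)) * scale > 0)
  expect_lt(abs(p - p_mc), 3 * sqrt(p * (1 - p) / n))
})

test_that("error probability is bounded and degrades to chance", {
  obs <- ri_uniform_obs()
  tr <- ri_trial_grid()
  pe <- error_probability(tr, obs, ri_prior)$p_error
  expect_true(all(pe <= 0.5 + 1e-12))
  same <- tibble::tibble(theta_l = 40, theta_r = 40, c_l = 1, c_r = 1)
  expect_equal(error_probability(same, obs, ri_prior)$p_error, 0.5)
  noisy <- ri_uniform_obs(sigma_late = 1e7)
  expect_equal(
    error_probability(
      tibble::tibble(theta_l = 90, theta_r = 20, c_l = 1, c_r = 1),
      noisy, ri_prior
    )$p_error, 0.5,
    tolerance = 1e-4
  )
})

test_that("mechanistic simulation is reproducible and consistent with the probit", {
  obs <- ri_uniform_obs(k_max = 25, sigma_late = 8)
  tr <- tibble::tibble(theta_l = 70, theta_r = 40, c_l = 1, c_r = 0.6)
  one <- simulate_choice(tr, obs, ri_prior, seed = 5)
  two <- simulate_choice(tr, obs, ri_prior, seed = 5)
  expect_identical(one, two)

  # noiseless limit: always correct on unequal stimuli
  sharp <- ri_uniform_obs(k_max = 5e4, sigma_late = 0)
  many <- tr[rep(1, 200), ]
  sim <- simulate_choice(many, sharp, ri_prior, seed = 2)
  expect_true(all(sim$choice == "left"))

  # Gaussian-approximation adequacy on a mouse-like trial grid
  grid <- ri_trial_grid()
  p_model <- choice_probability(grid, obs, ri_prior)$p_left
  n_rep <- 4000
  p_sim <- vapply(seq_len(nrow(grid)), function(i) {
    sim <- simulate_choice(grid[rep(i, n_rep), ], obs, ri_prior, seed = 30 + i)
    mean(sim$choice == "left")
  }, numeric(1))
  se <- sqrt(pmax(p_model * (1 - p_model), 1e-4) / n_rep)
  expect_true(all(abs(p_model - p_sim) < 0.02 + 3 * se))
})

test_that("the circular moment convention agrees at high precision", {
  obs_v <- ri_uniform_obs(k_max = 200, sigma_late = 3)
  obs_c <- ri_uniform_obs(k_max = 200, sigma_late = 3, convention = "circular")
  tr <- tibble::tibble(theta_l = c(60, 40), theta_r = c(30, 80), c_l = 1, c_r = 1)
  pv <- choice_probability(tr, obs_v, ri_prior)$p_left
  pc <- choice_probability(tr, obs_c, ri_prior)$p_left
  expect_equal(pv, pc, tolerance = 0.05)
})
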