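ri_pop <- function(k_max = 12, gain = resource_gain(c(0, 0, 0)),
                   n_neurons = 30, kappa_hat = 1.4, delta = 0.1) {
  population_code(ri_prior, gain, contrast_response(k_max, 2, 0.5),
    n_neurons = n_neurons, kappa_hat = kappa_hat, delta = delta
  )
}

test_that("preferred orientations are prior-proportional", {
  pop <- ri_pop(n_neurons = 120)
  v <- verticality(pop$preferred)
  # more neurons near horizontal than vertical for the horizontal-heavy prior
  expect_gt(sum(v <= 30), sum(v >= 60))
  expect_true(!is.unsorted(pop$preferred))
})

test_that("tuning curves have the stated peak, floor and half width", {
  pop <- ri_pop(delta = 0)
  f <- tuning(pop, pop$preferred[7], 1)
  kc <- k_of_contrast(pop$cr, 1)
  g7 <- pop$gain$g[pop$pref_idx[7]]
  expect_equal(f[1, 7], g7 * kc, tolerance = 1e-12)
  # zero contrast drive leaves only the base rate
  pop_d <- ri_pop(delta = 0.3)
  f0 <- tuning(pop_d, 40, 0)
  expect_true(all(abs(f0 - 0.3) < 1e-12))
  # half width from the closed form acos(1 - log(2) / kappa_hat)
  dpsi <- acos(1 - log(2) / pop$kappa_hat)
  theta_half <- pop$preferred[7] + dpsi * 90 / pi
  f_half <- tuning(pop, theta_half, 1)[1, 7]
  expect_equal(f_half, g7 * kc / 2, tolerance = 1e-9)
})

test_that("spike sampling is Poisson with the tuned means", {
  pop <- ri_pop()
  r1 <- sample_spikes(pop, 40, 0.6, n_draws = 5, seed = 3)
  expect_identical(r1, sample_spikes(pop, 40, 0.6, n_draws = 5, seed = 3))
  n <- 2e4
  r <- sample_spikes(pop, 40, 0.6, n_draws = n, seed = 4)
  f <- tuning(pop, 40, 0.6)[1, ]
  se <- sqrt(f / n)
  expect_true(all(abs(colMeans(r) - f) < 3.5 * se + 1e-3))
  # a zero-mean neuron never fires
  pop0 <- ri_pop(delta = 0)
  f0 <- tuning(pop0, 0, 1)[1, ]
  silent <- which(f0 < 1e-12)
  if (length(silent)) {
    r0 <- sample_spikes(pop0, 0, 1, n_draws = 100, seed = 5)
    expect_true(all(r0[, silent] == 0))
  }
})

test_that("BLS decoding recovers sharp single-neuron evidence and the prior mode", {
  pop <- ri_pop(k_max = 60, kappa_hat = 12, delta = 0)
  spikes <- rep(0, pop$n_neurons)
  # enough spikes that the tuning evidence dominates the silence term
  spikes[10] <- 300
  est <- decode_bls(pop, spikes, 1)
  expect_lt(abs(est - pop$preferred[10]), 4)
  # no spikes, flat tuning: estimate falls at the prior's circular mean
  pop_flat <- ri_pop(k_max = 1e-6, kappa_hat = 1.4, delta = 0.5)
  est0 <- decode_bls(pop_flat, rep(0, pop_flat$n_neurons), 1)
  expect_lt(verticality(est0), 12)
  expect_error(decode_bls(pop, c(1, 2), 1), "per neuron")
})

test_that("population decoding approaches a dense-support limit consistent with the observer", {
  # total population activity held fixed while the support densifies
  Ns <- c(30, 120, 480)
  mean_profiles <- lapply(Ns, function(N) {
    pop <- ri_pop(k_max = 12 * 30 / N, n_neurons = N, kappa_hat = 1.4, delta = 0.05)
    rattention:::.pop_decode_moments(pop, ri_prior, 1, n_sim = 60, seed = 6)$mean_v
  })
  gap_coarse <- sqrt(mean((mean_profiles[[2]] - mean_profiles[[1]])^2))
  gap_fine <- sqrt(mean((mean_profiles[[3]] - mean_profiles[[2]])^2))
  # support refinement changes the decode by no more than the Monte-Carlo
  # noise floor (measured by re-simulating the mid-size population)
  ref <- rattention:::.pop_decode_moments(
    ri_pop(k_max = 12 * 30 / 120, n_neurons = 120, kappa_hat = 1.4, delta = 0.05),
    ri_prior, 1,
    n_sim = 60, seed = 99
  )$mean_v
  floor_mc <- sqrt(mean((ref - mean_profiles[[2]])^2))
  expect_lt(gap_fine, 1.5 * floor_mc)
  expect_lt(gap_coarse, 1.5 * floor_mc)
  # dense decode mean tracks the algorithmic observer's bias profile
  obs <- ri_uniform_obs(k_max = 12, sigma_late = 0)
  mom <- estimator_moments(obs, ri_prior, ri_prior$theta, 1)
  expect_gt(cor(mean_profiles[[3]], mom$mean), 0.98)
})

test_that("the network objective decomposes and scales as stated", {
  pop <- ri_pop()
  env <- reward_environment("constant")
  obj0 <- network_objective(pop, env, 8, ri_prior, eta_spike = 0, n_sim = 30)
  expect_equal(obj0$objective, obj0$expected_reward)
  obj <- network_objective(pop, env, 8, ri_prior, eta_spike = 0.01, n_sim = 30)
  expect_equal(obj$objective, obj$expected_reward - 0.01 * obj$expected_spikes)

  # doubling all rates doubles the spike expectation exactly
  pop2 <- population_code(ri_prior, pop$gain,
    contrast_response(2 * pop$cr$k_max, 2, 0.5),
    n_neurons = 30, kappa_hat = 1.4, delta = 2 * pop$delta
  )
  s1 <- network_objective(pop, env, 8, ri_prior, n_sim = 5)$expected_spikes
  s2 <- network_objective(pop2, env, 8, ri_prior, n_sim = 5)$expected_spikes
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
})

test_that("expected spikes agree with direct simulation", {
  pop <- ri_pop()
  env <- reward_environment("constant")
  e_spk <- network_objective(pop, env, 8, ri_prior, n_sim = 5)$expected_spikes
  # simulate stimuli from the prior, both sides, all contrasts equally
  set.seed(8)
  n <- 4000
  th <- sample(ri_prior$theta, n, replace = TRUE, prob = ri_prior$density)
  cc <- sample(task_contrasts(), n, replace = TRUE)
  tot <- vapply(seq_len(n), function(i) {
    sum(rpois(pop$n_neurons, tuning(pop, th[i], cc[i])[1, ]))
  }, numeric(1))
  sim <- 2 * mean(tot)
  expect_lt(abs(sim - e_spk), 3 * 2 * sd(tot) / sqrt(n))
})
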