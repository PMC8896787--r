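test_that("average precision reduces to the separable closed form", {
  obs <- ri_uniform_obs(k_max = 20)
  # uniform gain: kbar = mean_c k(c) * sum(prior) = mean_c k(c)
  expect_equal(
    average_precision(obs, ri_prior, 0.6),
    k_of_contrast(obs$cr, 0.6),
    tolerance = 1e-12
  )
  expect_equal(
    average_precision(obs, ri_prior),
    mean(k_of_contrast(obs$cr, task_contrasts())),
    tolerance = 1e-12
  )
  # doubling gain at the prior peak raises the average
  g2 <- ri_prior$density * 0 + 1
  g2[1:5] <- 2
  obs2 <- observer_params(gain_from_values(g2), obs$cr, sigma_late = 8)
  expect_gt(average_precision(obs2, ri_prior), average_precision(obs, ri_prior))
})

test_that("mutual information is non-negative, increasing in precision, and matches a joint-entropy oracle", {
  flat_obs <- ri_uniform_obs(k_max = 1e-9)
  expect_lt(mutual_information_cost(flat_obs, ri_prior), 1e-6)
  mis <- vapply(c(5, 15, 45), function(k) {
    mutual_information_cost(ri_uniform_obs(k_max = k), ri_prior)
  }, numeric(1))
  expect_true(all(diff(mis) > 0))

  # oracle: I = H(theta) + H(m) - H(theta, m) from the explicit joint
  obs <- ri_uniform_obs(k_max = 10)
  kap <- k_of_contrast(obs$cr, 0.6) * obs$gain$g
  psi <- orientation_grid(2) * pi / 90
  L <- exp(outer(kap, rep(1, 90)) * (cos(outer(psi, psi, `-`)) - 1))
  L <- L / rowSums(L)
  joint <- L * ri_prior$density
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  oracle <- H(ri_prior$density) + H(colSums(joint)) - H(as.vector(joint))
  expect_equal(mutual_information_cost(obs, ri_prior, 0.6), oracle,
    tolerance = 1e-9
  )
})

test_that("expected loss captures the perfect and blind limits", {
  env <- reward_environment("increasing")
  sharp <- ri_uniform_obs(k_max = 5e4, sigma_late = 0)
  expect_lt(expected_loss(env, sharp, ri_prior), 0.05)
  # blind observer: P(error) = 0.5, loss = half the reward-weighted mass
  blind <- ri_uniform_obs(k_max = 1e-9, sigma_late = 1e7)
  m <- rattention:::.pair_mask(ri_prior, task_difficulties())
  rw <- rattention:::.pair_reward(env, m)
  expect_equal(expected_loss(env, blind, ri_prior), sum(m$w * rw) / 2,
    tolerance = 1e-6
  )
  # loss + reward = reward at stake, for any observer
  obs <- ri_uniform_obs(k_max = 8, sigma_late = 10)
  expect_equal(
    expected_loss(env, obs, ri_prior) + expected_reward(env, obs, ri_prior),
    sum(m$w * rw),
    tolerance = 1e-9
  )
})

test_that("optimization decomposes exactly and beats the uniform baseline", {
  env <- reward_environment("increasing")
  cost <- cost_model(0.16)
  opt <- optimize_gain(env, cost, 12, ri_prior, starts = 4, seed = 7)
  expect_equal(opt$objective, opt$loss + opt$cost, tolerance = 1e-8)
  # feasible-point comparison at the same k_max
  unif <- observer_params(
    resource_gain(c(0, 0, 0)),
    contrast_response(opt$k_max, 2, 0.5), 12
  )
  obj_unif <- expected_loss(env, unif, ri_prior, weighting = "dense") +
    0.16 * average_precision(unif, ri_prior)
  expect_lte(opt$objective, obj_unif + 1e-8)
})

test_that("a higher precision cost weakly lowers the optimized average precision", {
  env <- reward_environment("constant")
  kbars <- vapply(c(0.05, 0.4), function(eta) {
    opt <- optimize_gain(env, cost_model(eta), 8, ri_prior, starts = 4, seed = 3)
    average_precision(observer_from_opt(opt), ri_prior)
  }, numeric(1))
  expect_lte(kbars[2], kbars[1] + 1e-6)
})

test_that("optimization is reproducible under a fixed seed", {
  env <- reward_environment("decreasing")
  a <- optimize_gain(env, cost_model(0.1), 8, ri_prior, starts = 3, seed = 11)
  b <- optimize_gain(env, cost_model(0.1), 8, ri_prior, starts = 3, seed = 11)
  expect_identical(a$gain$g, b$gain$g)
  expect_identical(a$k_max, b$k_max)
})

test_that("swapping an environment's solution with itself loses nothing", {
  env <- reward_environment("increasing")
  cost <- cost_model(0.16)
  opt <- optimize_gain(env, cost, 12, ri_prior, starts = 3, seed = 5)
  res <- reward_loss_on_swap(env, env, cost, 12, ri_prior,
    opt_a = opt, opt_b = opt
  )
  expect_equal(res$percent_loss, 0, tolerance = 1e-10)
})

test_that("the mutual-information cost variant optimizes end to end", {
  opt <- optimize_gain(
    reward_environment("constant"), cost_model(0.3, "mutual_information"),
    8, ri_prior,
    starts = 2, seed = 1, maxit = 120
  )
  expect_equal(opt$objective, opt$loss + opt$cost, tolerance = 1e-8)
  expect_gt(opt$cost, 0)
})
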