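#' Poisson population code
#'
#' A bank of independent Poisson neurons with von Mises (bell-shaped)
#' tuning curves on the angle-doubled circle. Preferred orientations are
#' placed by the inverse CDF of the stimulus prior at quantile midpoints,
#' so their local density is proportional to the prior — which lets the
#' discrete Bayesian least-squares decoder drop the prior weights. The
#' expected spike count of neuron n for stimulus theta at contrast c is
#' `g(theta_n) * k(c) * exp(kappa_hat * (cos(psi_n - psi) - 1)) + delta`.
#'
#' @param prior An [orientation_prior()] tibble.
#' @param gain An [resource_gain()] object.
#' @param cr A [contrast_response()] object; its `k_max` is the peak rate
#'   `r_max` in spikes per trial.
#' @param n_neurons Number of neurons (>= 2), default 30.
#' @param kappa_hat Tuning width parameter; the default 1.4 gives a
#'   roughly 30 degree half-width at half-maximum and stands in for a
#'   value that would be estimated from population imaging.
#' @param delta Base firing rate at rest (spikes per trial).
#' @return A list of class `ri_pop`.
#' @export
population_code <- function(prior, gain, cr, n_neurons = 30,
                            kappa_hat = 1.4, delta = 0.1) {
  stopifnot(
    inherits(prior, "ri_prior"), inherits(gain, "ri_gain"),
    inherits(cr, "ri_contrast"), n_neurons >= 2, kappa_hat > 0, delta >= 0
  )
  cdf <- cumsum(prior$density)
  qs <- (seq_len(n_neurons) - 0.5) / n_neurons
  pref_idx <- findInterval(qs, c(0, cdf), rightmost.closed = TRUE)
  pref_idx <- pmin(pmax(pref_idx, 1), nrow(prior))
  preferred <- sort(prior$theta[pref_idx])
  structure(list(
    preferred = preferred,
    pref_idx = .grid_index(preferred, attr(prior, "step")),
    n_neurons = n_neurons, kappa_hat = kappa_hat, delta = delta,
    gain = gain, cr = cr, step = attr(prior, "step")
  ), class = "ri_pop")
}

#' Expected spike counts of the population
#'
#' @param pop An [population_code()] object.
#' @param theta Stimulus orientation(s) in degrees.
#' @param c Contrast.
#' @return A matrix of expected spike counts, `length(theta)` rows by
#'   `n_neurons` columns.
#' @export
tuning <- function(pop, theta, c) {
  stopifnot(inherits(pop, "ri_pop"))
  kc <- k_of_contrast(pop$cr, c)
  g_n <- pop$gain$g[pop$pref_idx]
  bump <- exp(pop$kappa_hat * (cos(outer(.psi(theta), .psi(pop$preferred), `-`)) - 1))
  sweep(bump, 2, g_n * kc, `*`) + pop$delta
}

#' Sample spike-count vectors
#'
#' Independent Poisson draws from the population's tuning for one
#' stimulus.
#'
#' @param pop An [population_code()] object.
#' @param theta Stimulus orientation in degrees (scalar).
#' @param c Contrast.
#' @param n_draws Number of population responses to draw.
#' @param seed Seed.
#' @return An `n_draws` by `n_neurons` matrix of spike counts.
#' @export
sample_spikes <- function(pop, theta, c, n_draws = 1, seed = 1) {
  f <- tuning(pop, theta, c)
  withr::with_seed(seed, {
    matrix(stats::rpois(n_draws * pop$n_neurons, rep(f, each = n_draws)),
      nrow = n_draws
    )
  })
}

# log f and column sums of f at the decode support (the preferred
# orientations), for one contrast
.decode_support <- function(pop, c) {
  FF <- tuning(pop, pop$preferred, c) # rows: support theta_n, cols: neuron m
  list(logF = log(pmax(t(FF), 1e-300)), sumF = rowSums(FF))
}

#' Discrete Bayesian least-squares decode of spike vectors
#'
#' Approximates the posterior-mean orientation by a sum over the
#' preferred-orientation support: weights
#' `L_n = exp(sum_m r_m log f_m(theta_n) - sum_m f_m(theta_n))` (prior
#' weights are absorbed by the prior-proportional spacing of the
#' support), combined as a circular mean in doubled-angle space.
#' Computed on the log scale with a log-sum-exp shift.
#'
#' @param pop An [population_code()] object.
#' @param spikes Spike-count vector, or matrix with one vector per row.
#' @param c Contrast at which the spikes were generated.
#' @return Decoded orientation(s) in degrees.
#' @export
decode_bls <- function(pop, spikes, c) {
  stopifnot(inherits(pop, "ri_pop"))
  if (is.null(dim(spikes))) spikes <- matrix(spikes, nrow = 1)
  if (ncol(spikes) != pop$n_neurons) {
    stop("spike vectors must have one count per neuron.", call. = FALSE)
  }
  sup <- .decode_support(pop, c)
  # logF[m, n] = log f_m(theta_n): rows index neurons, columns the support
  ll <- spikes %*% sup$logF # draws x support
  ll <- sweep(ll, 2, sup$sumF, `-`)
  ll <- ll - apply(ll, 1, max)
  W <- exp(ll)
  psi_n <- .psi(pop$preferred)
  S <- W %*% sin(psi_n)
  C <- W %*% cos(psi_n)
  if (any(S^2 + C^2 <= 0)) {
    stop("degenerate decode: zero resultant likelihood.", call. = FALSE)
  }
  .psi_to_theta(atan2(drop(S), drop(C)))
}

# Monte-Carlo verticality moments of the decoded estimate on the full
# stimulus grid, one contrast; fixed seed for a deterministic objective
.pop_decode_moments <- function(pop, prior, c, n_sim = 60, seed = 1) {
  theta <- prior$theta
  f <- tuning(pop, theta, c) # grid x neurons
  n <- length(theta)
  withr::with_seed(seed, {
    rates <- f[rep(seq_len(n), each = n_sim), ]
    R <- matrix(
      stats::rpois(length(rates), as.vector(rates)),
      nrow = nrow(rates)
    )
  })
  v <- matrix(verticality(decode_bls(pop, R, c)), nrow = n_sim)
  mean_v <- colMeans(v)
  var_v <- colMeans(v^2) - mean_v^2
  list(mean_v = mean_v, var_v = pmax(var_v, 0) * n_sim / (n_sim - 1))
}

#' Network objective: expected reward minus spike cost
#'
#' Expected per-trial reward of a decision stage reading out two
#' independent population decodes (late noise added on the decision
#' variable), minus `eta_spike` times the expected number of spikes the
#' two populations generate per trial. Decode moments are estimated by
#' Monte Carlo with a fixed internal seed; the spike expectation is
#' exact.
#'
#' @param pop An [population_code()] object.
#' @param env An [reward_environment()] object.
#' @param sigma_late Late-noise SD in verticality degrees.
#' @param prior An [orientation_prior()] tibble.
#' @param contrasts Contrast set.
#' @param eta_spike Cost per spike.
#' @param difficulties Stimulus-pair difficulty set.
#' @param n_sim Monte-Carlo draws per (stimulus, contrast).
#' @param seed Seed for the internal draws.
#' @return A one-row tibble with `expected_reward`, `expected_spikes`,
#'   `objective`.
#' @export
network_objective <- function(pop, env, sigma_late, prior,
                              contrasts = task_contrasts(), eta_spike = 0.01,
                              difficulties = task_difficulties(),
                              n_sim = 60, seed = 1) {
  stopifnot(inherits(pop, "ri_pop"), inherits(env, "ri_env"))
  mask <- .pair_mask(prior, difficulties)
  rw <- .pair_reward(env, mask)
  tabs <- stats::setNames(lapply(seq_along(contrasts), function(i) {
    .pop_decode_moments(pop, prior, contrasts[i], n_sim, seed + i)
  }), as.character(contrasts))
  acc <- .pair_accounting(tabs, contrasts, sigma_late, mask, rw)
  spikes_per_stim <- vapply(contrasts, function(cc) {
    sum(prior$density * rowSums(tuning(pop, prior$theta, cc)))
  }, numeric(1))
  e_spikes <- 2 * mean(spikes_per_stim) # two gratings per trial
  tibble::tibble(
    expected_reward = acc[["reward"]],
    expected_spikes = e_spikes,
    objective = acc[["reward"]] - eta_spike * e_spikes
  )
}

#' Optimize the population's gain and peak rate
#'
#' Maximizes [network_objective()] over the gain polynomial coefficients
#' and the peak rate `r_max` (log-parametrized), with the same polynomial
#' gain family and multi-start Nelder-Mead strategy as the algorithmic
#' model.
#'
#' @inheritParams network_objective
#' @param q,c50 Contrast response shape.
#' @param n_neurons,kappa_hat,delta Population architecture.
#' @param starts Number of starts.
#' @param opt_seed Seed for start draws.
#' @param r_max_range Search range for the peak rate (spikes/trial).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A list of class `ri_pop_opt` with the optimized `pop`,
#'   `r_max`, `gain`, the objective decomposition, and diagnostics.
#' @export
optimize_network <- function(env, eta_spike, sigma_late, prior,
                             contrasts = task_contrasts(),
                             q = 2, c50 = 0.5,
                             n_neurons = 30, kappa_hat = 1.4, delta = 0.1,
                             starts = 8, opt_seed = 1,
                             difficulties = task_difficulties(),
                             n_sim = 60, seed = 1,
                             r_max_range = c(1, 60), maxit = 150) {
  stopifnot(starts >= 1)
  step <- attr(prior, "step")
  build <- function(coef, r_max) {
    population_code(prior, resource_gain(coef, step = step),
      contrast_response(r_max, q = q, c50 = c50),
      n_neurons = n_neurons, kappa_hat = kappa_hat, delta = delta
    )
  }
  objective <- function(par) {
    coef <- par[1:3]
    if (!gain_coef_valid(coef)) {
      return(1e6 + sum(coef^2))
    }
    r_max <- exp(par[4])
    if (r_max < r_max_range[1] / 2 || r_max > r_max_range[2] * 2) {
      return(1e6 + abs(par[4]))
    }
    obj <- network_objective(
      build(coef, r_max), env, sigma_late, prior, contrasts,
      eta_spike, difficulties, n_sim, seed
    )
    -obj$objective
  }
  start_pars <- withr::with_seed(opt_seed, {
    sp <- replicate(starts - 1, {
      repeat {
        coef <- stats::runif(3, -1.2, 1.2)
        if (gain_coef_valid(coef)) break
      }
      c(coef, stats::runif(1, log(r_max_range[1]), log(r_max_range[2])))
    }, simplify = FALSE)
    c(list(c(0, 0, 0, mean(log(r_max_range)))), sp)
  })
  fits <- lapply(start_pars, function(p0) {
    stats::optim(p0, objective,
      method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-6)
    )
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  coef <- best$par[1:3]
  r_max <- exp(best$par[4])
  pop <- build(coef, r_max)
  obj <- network_objective(
    pop, env, sigma_late, prior, contrasts, eta_spike,
    difficulties, n_sim, seed
  )
  structure(list(
    pop = pop, gain = pop$gain, r_max = r_max,
    expected_reward = obj$expected_reward,
    expected_spikes = obj$expected_spikes,
    objective = obj$objective,
    env_id = env$env_id,
    settings = list(
      eta_spike = eta_spike, sigma_late = sigma_late, q = q, c50 = c50,
      n_neurons = n_neurons, kappa_hat = kappa_hat, delta = delta,
      starts = starts, opt_seed = opt_seed, n_sim = n_sim, seed = seed
    ),
    diagnostics = tibble::tibble(
      start = seq_along(fits), value = vals,
      convergence = vapply(fits, `[[`, numeric(1), "convergence")
    )
  ), class = "ri_pop_opt")
}
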