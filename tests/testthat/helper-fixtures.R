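# shared fixtures; everything is built in code, no files
ri_prior <- orientation_prior()

ri_uniform_obs <- function(k_max = 25, sigma_late = 8, ...) {
  observer_params(
    resource_gain(c(0, 0, 0)),
    contrast_response(k_max, q = 2, c50 = 0.5),
    sigma_late = sigma_late, ...
  )
}

# small grid of representative trials (no history)
ri_trial_grid <- function() {
  tidyr::expand_grid(
    theta_l = c(10, 40, 70, 90, 130),
    theta_r = c(30, 60, 110),
    c_l = c(0.3, 1),
    c_r = c(0.6, 1)
  )
}

# independent decode oracle: posterior mean on the doubled circle computed
# with plain loops, no package internals
ri_oracle_decode <- function(m_deg, kappa_vec, prior, step = 2) {
  theta <- seq(0, 180 - step, by = step)
  psi <- theta * pi / 90
  psim <- m_deg * pi / 90
  lik <- numeric(length(theta))
  for (i in seq_along(theta)) {
    li <- exp(kappa_vec[i] * (cos(psi[i] - psim) - 1))
    norm <- sum(exp(kappa_vec[i] * (cos(psi[i] - psi) - 1)))
    lik[i] <- li / norm
  }
  post <- lik * prior$density
  post <- post / sum(post)
  ang <- atan2(sum(post * sin(psi)), sum(post * cos(psi)))
  th <- (ang %% (2 * pi)) * 90 / pi
  if (th >= 180) th <- th - 180
  th
}
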