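#' Learning-rule parameters for the resource allocator
#'
#' The trial-by-trial allocator keeps a reward-belief vector over the
#' orientation grid and updates it after every choice with a
#' confidence-gated, sign-dependent learning rate and a von Mises
#' smoothing kernel; the resource gain function is the divisively
#' normalized belief.
#'
#' @param alpha_plus,alpha_minus Divisive learning-rate constants for
#'   positive and negative prediction errors (>= 0; the learning rate is
#'   `C / (C + alpha)`, so smaller constants mean faster learning).
#' @param k_tilde Kernel concentration (> 0) on the angle-doubled circle;
#'   larger values localize the update around the chosen orientation.
#' @param form How the von Mises kernel enters the prediction error.
#'   `"scaled"` (default) smooths the scalar error over the grid,
#'   `delta(theta) = (R - belief(theta_chosen)) * kern(theta - theta_chosen)`,
#'   which makes the belief converge to a kernel-smoothed map of received
#'   reward. `"literal"` applies the kernel to the belief term only,
#'   `delta(theta) = R - belief(theta_chosen) * kern(...)`; far from the
#'   chosen orientation this adds the raw reward every trial, which
#'   drives the normalized belief toward inverse choice occupancy rather
#'   than the reward map (kept for comparison; see the methods
#'   vignette).
#' @return A list of class `ri_rl`.
#' @export
rl_params <- function(alpha_plus = 50, alpha_minus = 50, k_tilde = 1.4,
                      form = c("scaled", "literal")) {
  stopifnot(alpha_plus >= 0, alpha_minus >= 0, k_tilde > 0)
  structure(list(
    alpha_plus = alpha_plus, alpha_minus = alpha_minus,
    k_tilde = k_tilde, form = match.arg(form)
  ), class = "ri_rl")
}

#' Reward belief vector
#'
#' Nonnegative reward expectations (ul) over the orientation grid,
#' initialized uniform at the constant-environment reward of 5 ul.
#'
#' @param value Initial belief per grid point.
#' @param step Grid step in degrees.
#' @return A tibble of class `ri_belief` with columns `theta`, `value`.
#' @export
reward_belief <- function(value = 5, step = 2) {
  theta <- orientation_grid(step)
  value <- rep_len(value, length(theta))
  if (any(value < 0)) stop("belief values must be >= 0.", call. = FALSE)
  out <- tibble::tibble(theta = theta, value = value)
  attr(out, "step") <- step
  class(out) <- c("ri_belief", class(out))
  out
}

#' Decision confidence
#'
#' Model probability that the chosen side is correct, from the observer's
#' bias-free choice probability: `max(p_left, 1 - p_left)`. Always in
#' `[0.5, 1]`; equals 0.5 when the two stimuli are indistinguishable.
#'
#' @param trials Trial table (choices not needed; confidence is
#'   choice-symmetric under the bias-free rule).
#' @param obs An [observer_params()] object.
#' @param prior An [orientation_prior()] tibble.
#' @return The input tibble with a `confidence` column appended.
#' @export
confidence <- function(trials, obs, prior) {
  z <- .choice_z(trials, obs, prior, with_bias = FALSE)
  p <- stats::pnorm(z)
  dplyr::mutate(tibble::as_tibble(trials), confidence = pmax(p, 1 - p))
}

#' Confidence-gated learning rate
#'
#' `alpha_t = C / (C + alpha_tilde)`, with `alpha_tilde` chosen by the
#' sign of the prediction error at the chosen orientation. As
#' `alpha_tilde -> 0` the rate tends to 1 and confidence loses influence.
#'
#' @param conf Confidence value(s) in `(0, 1]`.
#' @param delta_sign Sign of the prediction error (`delta <= 0` selects
#'   `alpha_minus`).
#' @param params An [rl_params()] object.
#' @return Learning rate(s) in `(0, 1]`.
#' @export
learning_rate <- function(conf, delta_sign, params) {
  stopifnot(inherits(params, "ri_rl"), all(conf > 0), all(conf <= 1))
  a <- ifelse(delta_sign > 0, params$alpha_plus, params$alpha_minus)
  conf / (conf + a)
}

#' Prediction error vector
#'
#' Distributional prediction error over the orientation grid after
#' receiving reward `R` for choosing orientation `theta_chosen`, smoothed
#' by a von Mises kernel in doubled-angle space (see [rl_params()] for
#' the two kernel forms). At the chosen orientation the kernel equals 1
#' and both forms reduce to the scalar prediction error
#' `R - belief(theta_chosen)`.
#'
#' @param reward Received reward (ul).
#' @param theta_chosen Chosen orientation in degrees (snapped to grid).
#' @param belief An [reward_belief()] tibble.
#' @param params An [rl_params()] object.
#' @return Numeric vector of per-grid-point prediction errors.
#' @export
prediction_error_vector <- function(reward, theta_chosen, belief, params) {
  stopifnot(inherits(belief, "ri_belief"), inherits(params, "ri_rl"))
  step <- attr(belief, "step")
  i <- .grid_index(theta_chosen, step)
  kern <- exp(params$k_tilde * (cos(.psi(belief$theta[i]) - .psi(belief$theta)) - 1))
  if (params$form == "scaled") {
    (reward - belief$value[i]) * kern
  } else {
    reward - belief$value[i] * kern
  }
}

#' One learning update with divisive normalization
#'
#' Applies the confidence-gated update `belief <- belief + alpha * delta`
#' (floored at zero so the belief stays a valid allocation) and returns
#' both the new belief and the divisively normalized resource gain
#' `g = belief / sum(belief)`.
#'
#' @param belief An [reward_belief()] tibble.
#' @param reward Received reward (ul).
#' @param theta_chosen Chosen orientation in degrees.
#' @param conf Decision confidence in `(0, 1]`.
#' @param params An [rl_params()] object.
#' @return A list with elements `belief` (updated `ri_belief`) and `gain`
#'   (an `ri_gain`; sums to 1 before the mean-1 rescaling used for
#'   encoding).
#' @export
update_and_normalize <- function(belief, reward, theta_chosen, conf, params) {
  delta <- prediction_error_vector(reward, theta_chosen, belief, params)
  i <- .grid_index(theta_chosen, attr(belief, "step"))
  alpha <- learning_rate(conf, sign(delta[i]), params)
  new_val <- pmax(belief$value + alpha * delta, 0)
  if (sum(new_val) <= 0) {
    stop("degenerate reward belief: all mass removed.", call. = FALSE)
  }
  new_belief <- belief
  new_belief$value <- new_val
  list(
    belief = new_belief,
    gain = gain_from_values(new_val / sum(new_val),
      step = attr(belief, "step"), floor = 1e-8
    )
  )
}

#' Closed-loop reinforcement-learning session
#'
#' Runs the allocator through a stimulus stream: every trial's choice is
#' simulated from the observer using the current learned gain, the
#' reward and confidence feed the distributional update, and the
#' normalized belief becomes the next trial's gain. Reproducible per
#' seed.
#'
#' @param trials Stimulus-only trial table (e.g. from
#'   [generate_trials()]); the `env_id` column sets the reward mapping
#'   per trial, so mid-stream environment switches are supported.
#' @param obs Observer providing the contrast response, late noise and
#'   biases; its gain is replaced by the learned gain each trial.
#' @param prior An [orientation_prior()] tibble.
#' @param params An [rl_params()] object.
#' @param belief Initial [reward_belief()].
#' @param seed Seed.
#' @return A list of class `ri_rl_run` with `trials` (choices, rewards,
#'   confidence appended), `g_trace` (trials x grid matrix of gains,
#'   each row summing to 1), `belief` (final), and `grid`.
#' @export
run_rl_session <- function(trials, obs, prior, params = rl_params(),
                           belief = reward_belief(), seed = 1) {
  stopifnot(inherits(obs, "ri_observer"), inherits(params, "ri_rl"))
  step <- attr(prior, "step")
  n <- nrow(trials)
  ngrid <- nrow(belief)
  g_trace <- matrix(NA_real_, n, ngrid)
  choice <- character(n)
  rewards <- conf_v <- numeric(n)
  envs <- lapply(
    stats::setNames(nm = unique(trials$env_id)),
    reward_environment
  )
  il <- .grid_index(trials$theta_l, step)
  ir <- .grid_index(trials$theta_r, step)
  psil <- .psi(trials$theta_l)
  psir <- .psi(trials$theta_r)
  kl <- k_of_contrast(obs$cr, trials$c_l)
  kr <- k_of_contrast(obs$cr, trials$c_r)
  psi_grid <- .psi(prior$theta)
  rownorm <- function(kappa) {
    # measurement-grid normalizer of a von Mises at concentration kappa;
    # the grid is uniform so the normalizer is location-free
    sum(exp(kappa * (cos(psi_grid) - 1)))
  }
  withr::with_seed(seed, {
    val <- belief$value
    for (t in seq_len(n)) {
      g <- val / sum(val)
      g_enc <- pmax(g, 1e-8 * max(g))
      g_enc <- g_enc / mean(g_enc)
      g_trace[t, ] <- g
      # sample a measurement and decode, per side
      vhat <- numeric(2)
      kaps <- c(kl[t] * g_enc[il[t]], kr[t] * g_enc[ir[t]])
      psis <- c(psil[t], psir[t])
      for (s in 1:2) {
        pm <- exp(kaps[s] * (cos(psi_grid - psis[s]) - 1))
        m <- sample.int(ngrid, 1, prob = pm)
        kap_all <- pmax(c(kl[t], kr[t])[s] * g_enc, 1e-12)
        lik <- exp(kap_all * (cos(psi_grid - psi_grid[m]) - 1)) /
          vapply(kap_all, rownorm, numeric(1))
        post <- lik * prior$density
        vhat[s] <- verticality(.psi_to_theta(atan2(
          sum(post * sin(psi_grid)), sum(post * cos(psi_grid))
        )))
      }
      dv <- vhat[1] - vhat[2] + stats::rnorm(1, 0, obs$sigma_late)
      choice[t] <- if (dv > 0) "left" else if (dv < 0) "right" else sample(c("left", "right"), 1)
      # bias-free confidence from the current gain's moment tables would be
      # exact but costly; use the trial's realized estimate distribution via
      # the probit with current precisions
      obs_t <- observer_params(gain_from_values(g_enc, step, floor = 1e-8),
        obs$cr,
        sigma_late = obs$sigma_late
      )
      conf_v[t] <- confidence(trials[t, ], obs_t, prior)$confidence
      theta_ch <- if (choice[t] == "left") trials$theta_l[t] else trials$theta_r[t]
      is_tie <- isTRUE(trials$tie[t]) ||
        abs(verticality(trials$theta_l[t]) - verticality(trials$theta_r[t])) < 1e-9
      got <- if (is_tie) {
        stats::runif(1) < 0.5
      } else {
        corr_side <- if (verticality(trials$theta_l[t]) > verticality(trials$theta_r[t])) "left" else "right"
        choice[t] == corr_side
      }
      env_t <- envs[[trials$env_id[t]]]
      rewards[t] <- if (got) reward_for(env_t, theta_ch) else 0
      # distributional update
      ich <- .grid_index(theta_ch, step)
      kern <- exp(params$k_tilde * (cos(psi_grid[ich] - psi_grid) - 1))
      delta <- if (params$form == "scaled") {
        (rewards[t] - val[ich]) * kern
      } else {
        rewards[t] - val[ich] * kern
      }
      alpha <- learning_rate(conf_v[t], sign(delta[ich]), params)
      val <- pmax(val + alpha * delta, 0)
      if (sum(val) <= 0) stop("degenerate reward belief.", call. = FALSE)
    }
  })
  final <- belief
  final$value <- val
  structure(list(
    trials = dplyr::mutate(tibble::as_tibble(trials),
      choice = choice, reward = rewards, confidence = conf_v
    ),
    g_trace = g_trace,
    belief = final,
    grid = prior$theta,
    params = params,
    seed = seed
  ), class = "ri_rl_run")
}

#' Time-averaged learned gain
#'
#' Mean of the learned gain over the last `window` trials of a session,
#' as an `ri_gain` (useful for comparing against the static optimum).
#'
#' @param run An `ri_rl_run` from [run_rl_session()].
#' @param window Number of trailing trials to average.
#' @return An `ri_gain` tibble.
#' @export
mean_gain <- function(run, window = 500) {
  stopifnot(inherits(run, "ri_rl_run"))
  n <- nrow(run$g_trace)
  rows <- max(1, n - window + 1):n
  gain_from_values(colMeans(run$g_trace[rows, , drop = FALSE]),
    step = attr(run$belief, "step")
  )
}
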