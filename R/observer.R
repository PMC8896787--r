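#' Rational-inattention observer parameters
#'
#' Bundles the components of the Bayesian observer: a resource gain
#' function distributing encoding precision over orientation space, a
#' contrast response function setting overall precision per contrast, late
#' (post-decoding) Gaussian noise on the decision variable, and probit
#' choice biases. Encoding precision for stimulus `theta` at contrast `c`
#' is the product `k(c) * g(theta)`. The lapse rate of this model family is
#' fixed at zero; apparent lapses are rationalized by the encoding model.
#'
#' @param gain An [resource_gain()] object.
#' @param cr A [contrast_response()] object.
#' @param sigma_late Late-noise standard deviation in verticality degrees
#'   (>= 0).
#' @param beta0 Side bias.
#' @param beta1 Previous-choice bias; multiplies D = +1 after a left
#'   choice, -1 after a right choice, 0 on first trials.
#' @param beta2 Contrast-difference bias; multiplies `c_l - c_r`.
#' @param convention How estimator moments are summarized before the
#'   probit decision stage. `"verticality"` (default) folds each decoded
#'   estimate into verticality space and takes its linear mean/variance;
#'   `"circular"` takes circular moments of the decoded orientation and
#'   folds the circular mean.
#' @return A list of class `ri_observer`.
#' @export
observer_params <- function(gain, cr, sigma_late = 0,
                            beta0 = 0, beta1 = 0, beta2 = 0,
                            convention = c("verticality", "circular")) {
  stopifnot(inherits(gain, "ri_gain"), inherits(cr, "ri_contrast"))
  stopifnot(sigma_late >= 0, is.finite(c(beta0, beta1, beta2)))
  convention <- match.arg(convention)
  structure(
    list(
      gain = gain, cr = cr, sigma_late = sigma_late,
      beta0 = beta0, beta1 = beta1, beta2 = beta2,
      convention = convention
    ),
    class = "ri_observer"
  )
}

# ---- internal numerical engine ------------------------------------------

.ri_cache <- new.env(parent = emptyenv())

# cos(psi_i - psi_j) - 1 on the doubled-angle grid; memoized per step
.cos_diff <- function(step) {
  key <- paste0("cosdiff_", step)
  if (is.null(.ri_cache[[key]])) {
    psi <- .psi(orientation_grid(step))
    .ri_cache[[key]] <- cos(outer(psi, psi, `-`)) - 1
  }
  .ri_cache[[key]]
}

# Measurement distribution rows: P[i, j] = p(m_j | theta_i), each row a
# grid-normalized von Mises with concentration kappa[i].
.measurement_rows <- function(kappa, step) {
  L <- exp(.cos_diff(step) * kappa)
  L / rowSums(L)
}

# Per-measurement BLS decode table and moment vectors for one contrast.
# kappa is the length-n concentration vector k(c) * g(theta).
.contrast_table <- function(kappa, prior, convention = "verticality") {
  step <- attr(prior, "step")
  theta <- prior$theta
  psi <- .psi(theta)
  P <- .measurement_rows(kappa, step)
  # posterior over theta for each measurement column; circular mean decode
  W <- P * prior$density
  S <- colSums(W * sin(psi))
  C <- colSums(W * cos(psi))
  R2 <- S^2 + C^2
  if (any(R2 <= 0)) {
    stop("degenerate posterior (zero resultant) while decoding.", call. = FALSE)
  }
  theta_hat <- .psi_to_theta(atan2(S, C))
  v_hat <- verticality(theta_hat)
  if (convention == "verticality") {
    mean_v <- drop(P %*% v_hat)
    var_v <- pmax(drop(P %*% v_hat^2) - mean_v^2, 0)
  } else {
    psi_hat <- .psi(theta_hat)
    a <- drop(P %*% sin(psi_hat))
    b <- drop(P %*% cos(psi_hat))
    r2 <- a^2 + b^2
    if (any(r2 <= 0)) stop("a^2 + b^2 <= 0 in circular moments.", call. = FALSE)
    mean_v <- verticality(.psi_to_theta(atan2(a, b)))
    var_v <- pmax(-2 * log(r2), 0) * (90 / pi)^2
  }
  list(
    theta = theta, kappa = kappa, P = P, theta_hat = theta_hat,
    v_hat = v_hat, mean_v = mean_v, var_v = var_v
  )
}

# Tables for every contrast in `contrasts`, given a gain vector and a
# contrast response function.
.observer_tables <- function(obs, prior, contrasts) {
  g <- obs$gain$g
  stats::setNames(
    lapply(contrasts, function(cc) {
      .contrast_table(k_of_contrast(obs$cr, cc) * g, prior, obs$convention)
    }),
    as.character(contrasts)
  )
}

.grid_index <- function(theta, step) {
  i <- round(theta / step) %% (180 / step) + 1L
  as.integer(i)
}

.prev_D <- function(prev_choice) {
  d <- ifelse(prev_choice == "left", 1, ifelse(prev_choice == "right", -1, 0))
  d[is.na(d)] <- 0
  d
}

# ---- exported operations -------------------------------------------------

#' Measurement density for a stimulus
#'
#' Discrete von Mises density of the internal measurement m given a
#' stimulus, with concentration `k(c) * g(theta0)` on the angle-doubled
#' circle, normalized to sum to one over the measurement grid.
#'
#' @param theta0 Stimulus orientation in degrees.
#' @param c Contrast.
#' @param obs An [observer_params()] object.
#' @param step Grid step in degrees.
#' @return A tibble with columns `m` (degrees) and `density`.
#' @export
measurement_density <- function(theta0, c, obs, step = 2) {
  stopifnot(inherits(obs, "ri_observer"), length(theta0) == 1)
  theta <- orientation_grid(step)
  if (length(theta) == 0) stop("empty measurement grid.", call. = FALSE)
  g0 <- obs$gain$g[.grid_index(theta0, step)]
  kap <- k_of_contrast(obs$cr, c) * g0
  dens <- exp(kap * (cos(.psi(theta) - .psi(theta0)) - 1))
  tibble::tibble(m = theta, density = dens / sum(dens))
}

#' Bayesian least-squares estimate of orientation
#'
#' Posterior-mean (circular mean on the angle-doubled circle) decode of a
#' measurement, combining the grid-normalized von Mises likelihood with
#' the orientation prior.
#'
#' @param m Measurement orientation(s) in degrees (snapped to the grid).
#' @param obs An [observer_params()] object.
#' @param prior An [orientation_prior()] tibble.
#' @param c Contrast at which the measurement was made.
#' @return Estimated orientation(s) in degrees on `[0, 180)`.
#' @export
bls_estimate <- function(m, obs, prior, c) {
  stopifnot(inherits(obs, "ri_observer"), inherits(prior, "ri_prior"))
  tab <- .contrast_table(k_of_contrast(obs$cr, c) * obs$gain$g, prior,
    convention = obs$convention
  )
  tab$theta_hat[.grid_index(m, attr(prior, "step"))]
}

#' Moments of the orientation estimator
#'
#' Mean and variance of the decoded estimate conditional on the true
#' stimulus, obtained by integrating the decode table over the measurement
#' distribution. Under the default `"verticality"` convention the decoded
#' orientation is folded into verticality space first and linear moments
#' are taken there; these moments feed the probit decision stage.
#'
#' @param obs An [observer_params()] object.
#' @param prior An [orientation_prior()] tibble.
#' @param theta0 Stimulus orientation(s) in degrees.
#' @param c Contrast level(s); scalar or vector matching `theta0`.
#' @return A tibble with columns `theta0`, `contrast`, `mean` (verticality
#'   degrees) and `var` (degrees squared).
#' @export
estimator_moments <- function(obs, prior, theta0, c) {
  stopifnot(inherits(obs, "ri_observer"), inherits(prior, "ri_prior"))
  cc <- rep_len(c, length(theta0))
  step <- attr(prior, "step")
  tabs <- .observer_tables(obs, prior, sort(unique(cc)))
  idx <- .grid_index(theta0, step)
  mean_v <- var_v <- numeric(length(theta0))
  for (u in names(tabs)) {
    sel <- cc == as.numeric(u)
    mean_v[sel] <- tabs[[u]]$mean_v[idx[sel]]
    var_v[sel] <- tabs[[u]]$var_v[idx[sel]]
  }
  tibble::tibble(theta0 = theta0, contrast = cc, mean = mean_v, var = var_v)
}

#' Probability of choosing the left stimulus
#'
#' Probit choice rule of the rational-inattention observer: the decision
#' variable is the difference of expected verticality estimates scaled by
#' the total (estimation plus late) noise, shifted by side,
#' previous-choice, and contrast-difference biases.
#'
#' @param trials A trial table (tibble/data frame) with columns `theta_l`,
#'   `theta_r`, `c_l`, `c_r`, and optionally `prev_choice`
#'   (`"left"`/`"right"`/`"none"`).
#' @param obs An [observer_params()] object.
#' @param prior An [orientation_prior()] tibble.
#' @return The input tibble with a `p_left` column appended.
#' @export
choice_probability <- function(trials, obs, prior) {
  z <- .choice_z(trials, obs, prior, with_bias = TRUE)
  dplyr::mutate(tibble::as_tibble(trials), p_left = stats::pnorm(z))
}

.choice_z <- function(trials, obs, prior, with_bias = TRUE,
                      tabs = NULL) {
  stopifnot(inherits(obs, "ri_observer"), inherits(prior, "ri_prior"))
  step <- attr(prior, "step")
  cs <- sort(unique(c(trials$c_l, trials$c_r)))
  if (is.null(tabs)) tabs <- .observer_tables(obs, prior, cs)
  il <- .grid_index(trials$theta_l, step)
  ir <- .grid_index(trials$theta_r, step)
  n <- nrow(trials)
  ml <- vl <- mr <- vr <- numeric(n)
  for (u in names(tabs)) {
    sl <- trials$c_l == as.numeric(u)
    sr <- trials$c_r == as.numeric(u)
    ml[sl] <- tabs[[u]]$mean_v[il[sl]]
    vl[sl] <- tabs[[u]]$var_v[il[sl]]
    mr[sr] <- tabs[[u]]$mean_v[ir[sr]]
    vr[sr] <- tabs[[u]]$var_v[ir[sr]]
  }
  vsum <- vl + vr + obs$sigma_late^2
  if (any(vsum < 0)) {
    stop("negative variance sum: probit decision variable undefined.", call. = FALSE)
  }
  denom <- sqrt(vsum)
  z <- (ml - mr) / denom
  # noiseless limit: the decision is determined by the sign of the contrast
  if (any(denom == 0)) {
    d0 <- denom == 0
    z[d0] <- sign(ml[d0] - mr[d0]) * Inf
    z[d0 & ml == mr] <- 0
  }
  if (with_bias) {
    D <- if ("prev_choice" %in% names(trials)) .prev_D(trials$prev_choice) else 0
    z <- z + obs$beta0 + obs$beta1 * D + obs$beta2 * (trials$c_l - trials$c_r)
  }
  z
}

#' Probability of an erroneous choice
#'
#' Bias-free error probability
#' `Phi(-|E_l - E_r| / sqrt(Var_l + Var_r + sigma_late^2))`; at most 0.5.
#'
#' @inheritParams choice_probability
#' @return The input tibble with a `p_error` column appended.
#' @export
error_probability <- function(trials, obs, prior) {
  z <- .choice_z(trials, obs, prior, with_bias = FALSE)
  dplyr::mutate(tibble::as_tibble(trials), p_error = stats::pnorm(-abs(z)))
}

#' Simulate observer choices mechanistically
#'
#' Samples a measurement for each side from its von Mises distribution,
#' decodes it by Bayesian least squares, folds to verticality, adds late
#' Gaussian noise and the bias terms, and applies the decision rule.
#' Reproducible for a fixed seed.
#'
#' @inheritParams choice_probability
#' @param seed Integer seed.
#' @return The input tibble with `vhat_l`, `vhat_r` (realized verticality
#'   estimates) and `choice` (`"left"`/`"right"`) columns appended.
#' @export
simulate_choice <- function(trials, obs, prior, seed = 1) {
  stopifnot(inherits(obs, "ri_observer"), inherits(prior, "ri_prior"))
  step <- attr(prior, "step")
  cs <- sort(unique(c(trials$c_l, trials$c_r)))
  tabs <- .observer_tables(obs, prior, cs)
  n <- nrow(trials)
  il <- .grid_index(trials$theta_l, step)
  ir <- .grid_index(trials$theta_r, step)
  withr::with_seed(seed, {
    vhat_l <- .sample_vhat(tabs, trials$c_l, il)
    vhat_r <- .sample_vhat(tabs, trials$c_r, ir)
    D <- if ("prev_choice" %in% names(trials)) .prev_D(trials$prev_choice) else 0
    dv <- vhat_l - vhat_r + stats::rnorm(n, 0, obs$sigma_late)
    # bias terms act on the standardized probit scale; rescale them onto
    # the decision-variable scale used by the mechanistic simulation
    scale <- sqrt(.total_var(tabs, trials, il, ir) + obs$sigma_late^2)
    dv <- dv + (obs$beta0 + obs$beta1 * D +
      obs$beta2 * (trials$c_l - trials$c_r)) * scale
    choice <- ifelse(dv > 0, "left", ifelse(dv < 0, "right",
      sample(c("left", "right"), n, replace = TRUE)
    ))
  })
  dplyr::mutate(tibble::as_tibble(trials),
    vhat_l = vhat_l, vhat_r = vhat_r, choice = choice
  )
}

.sample_vhat <- function(tabs, contrast, idx) {
  out <- numeric(length(idx))
  ngrid <- length(tabs[[1]]$v_hat)
  for (u in names(tabs)) {
    sel <- which(contrast == as.numeric(u))
    if (!length(sel)) next
    P <- tabs[[u]]$P
    v <- tabs[[u]]$v_hat
    for (i in sel) {
      m <- sample.int(ngrid, 1, prob = P[idx[i], ])
      out[i] <- v[m]
    }
  }
  out
}

.total_var <- function(tabs, trials, il, ir) {
  vl <- vr <- numeric(nrow(trials))
  for (u in names(tabs)) {
    sl <- trials$c_l == as.numeric(u)
    sr <- trials$c_r == as.numeric(u)
    vl[sl] <- tabs[[u]]$var_v[il[sl]]
    vr[sr] <- tabs[[u]]$var_v[ir[sr]]
  }
  vl + vr
}
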