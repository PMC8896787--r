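#' Verticality mapping
#'
#' Folds an orientation on `[0, 180)` degrees into the abstract verticality
#' coordinate `90 - |90 - theta|`, so that 0 and 180 degrees (horizontal)
#' map to 0 and 90 degrees (vertical) maps to 90. The task's decision rule
#' ("choose the more vertical grating") and all probit decision variables
#' operate in this space.
#'
#' @param theta Numeric vector of orientations in degrees on `[0, 180)`.
#'   Values on `[0, 90]` are fixed points.
#' @return Numeric vector of verticality values on `[0, 90]`.
#' @examples
#' verticality(c(0, 45, 90, 170))
#' @export
verticality <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite numeric degrees.", call. = FALSE)
  }
  if (any(theta < 0 | theta >= 180 + 1e-9)) {
    stop("`theta` must lie in [0, 180) degrees.", call. = FALSE)
  }
  90 - abs(90 - theta)
}

# doubled-angle coordinate: psi = 2 * theta in radians, period 2*pi.
# All circular computations (von Mises likelihoods, circular means) live here.
.psi <- function(theta_deg) theta_deg * pi / 90

.psi_to_theta <- function(psi) {
  theta <- (psi %% (2 * pi)) * 90 / pi
  theta[theta >= 180] <- theta[theta >= 180] - 180
  theta
}

#' Orientation grid
#'
#' Regular grid over orientation space `[0, 180)` degrees. The default 2
#' degree step is shared by the observer's measurement grid and the
#' reinforcement-learning reward-belief vector (0 to 178 degrees).
#'
#' @param step Grid step in degrees; must divide 180.
#' @return Numeric vector of grid orientations in degrees.
#' @export
orientation_grid <- function(step = 2) {
  if (step <= 0 || abs(180 / step - round(180 / step)) > 1e-9) {
    stop("`step` must be a positive divisor of 180.", call. = FALSE)
  }
  seq(0, 180 - step, by = step)
}

#' Horizontal-heavy orientation prior
#'
#' Discrete prior over the orientation grid with more mass at horizontal
#' than at vertical orientations, as in the mouse task. The density is a
#' von Mises on the angle-doubled circle centred at horizontal,
#' `pi(theta) proportional to exp(concentration * cos(2 * theta))`, so it is
#' symmetric about 90 degrees and peaks at 0/180 degrees. The functional
#' form is a modelling choice exposed here so alternative priors can be
#' swapped in.
#'
#' @param step Grid step in degrees (default 2).
#' @param concentration Shape parameter (>= 0) of the horizontal peak. The
#'   default 0.5 puts roughly `exp(1) ~ 2.7` times more mass at horizontal
#'   than at vertical orientations.
#' @return A tibble of class `ri_prior` with columns `theta` (degrees) and
#'   `density` (sums to 1), and attributes `step` and `concentration`.
#' @examples
#' pr <- orientation_prior()
#' sum(pr$density)
#' @export
orientation_prior <- function(step = 2, concentration = 0.5) {
  stopifnot(concentration >= 0)
  theta <- orientation_grid(step)
  dens <- exp(concentration * cos(.psi(theta)))
  dens <- dens / sum(dens)
  out <- tibble::tibble(theta = theta, density = dens)
  attr(out, "step") <- step
  attr(out, "concentration") <- concentration
  class(out) <- c("ri_prior", class(out))
  out
}

#' Sample orientations from a prior
#'
#' @param prior An [orientation_prior()] tibble.
#' @param n Number of draws.
#' @return Numeric vector of grid orientations in degrees.
#' @keywords internal
sample_prior <- function(prior, n) {
  prior$theta[sample.int(nrow(prior), n, replace = TRUE, prob = prior$density)]
}

#' Stimulus-reward environments
#'
#' The three reward mappings of the task. In all environments the correct
#' choice is the more vertical grating; the reward delivered for a correct
#' choice depends on the correct-side orientation:
#' * `"constant"` - 5 ul everywhere;
#' * `"increasing"` - linear in verticality, 1 ul at horizontal up to 8 ul
#'   at vertical;
#' * `"decreasing"` - the reverse, 8 ul at horizontal down to 1 ul at
#'   vertical.
#'
#' @param env_id One of `"constant"`, `"increasing"`, `"decreasing"`.
#' @return A list of class `ri_env` with elements `env_id` and `reward_fun`
#'   (verticality degrees -> microlitres).
#' @examples
#' reward_for(reward_environment("increasing"), 90)
#' @export
reward_environment <- function(env_id = c("constant", "increasing", "decreasing")) {
  env_id <- match.arg(env_id)
  reward_fun <- switch(env_id,
    constant = function(v) rep_len(5, length(v)),
    increasing = function(v) 1 + 7 * v / 90,
    decreasing = function(v) 8 - 7 * v / 90
  )
  structure(list(env_id = env_id, reward_fun = reward_fun), class = "ri_env")
}

#' Reward for an orientation
#'
#' Evaluates an environment's reward map at an orientation (folded to
#' verticality first).
#'
#' @param env An [reward_environment()] object.
#' @param theta Orientation(s) in degrees on `[0, 180)`.
#' @return Reward in microlitres.
#' @export
reward_for <- function(env, theta) {
  if (!inherits(env, "ri_env")) {
    stop("`env` must be created by reward_environment().", call. = FALSE)
  }
  env$reward_fun(verticality(theta))
}

#' Contrast response function
#'
#' Saturating (Naka-Rushton) map from stimulus contrast to encoding
#' precision: `k(c) = k_max * c^q / (c^q + c50^q)`. Precision is expressed
#' in von Mises concentration units on the angle-doubled circle.
#'
#' @param k_max Peak precision (> 0).
#' @param q Slope exponent (> 0).
#' @param c50 Semisaturation contrast in (0, 1].
#' @return A list of class `ri_contrast`.
#' @examples
#' cr <- contrast_response(k_max = 20)
#' k_of_contrast(cr, c(0.3, 0.6, 1))
#' @export
contrast_response <- function(k_max, q = 2, c50 = 0.5) {
  stopifnot(k_max > 0, q > 0, c50 > 0, c50 <= 1)
  structure(list(k_max = k_max, q = q, c50 = c50), class = "ri_contrast")
}

#' Encoding precision at a contrast
#'
#' @param cr A [contrast_response()] object.
#' @param c Contrast value(s) in `[0, 1]`.
#' @return Precision (von Mises concentration) values.
#' @export
k_of_contrast <- function(cr, c) {
  if (!inherits(cr, "ri_contrast")) {
    stop("`cr` must be created by contrast_response().", call. = FALSE)
  }
  if (any(c < 0)) stop("contrast must be non-negative.", call. = FALSE)
  cq <- c^cr$q
  cr$k_max * cq / (cq + cr$c50^cr$q)
}

#' Default task contrast set
#' @return The three contrast levels used in the task.
#' @export
task_contrasts <- function() c(0.3, 0.6, 1)
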