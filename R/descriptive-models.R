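#' Descriptive probit choice model parameters
#'
#' The six descriptive models (DM1-DM6) are probit psychometric models on
#' the verticality difference of the two gratings, with optional
#' contrast-dependent noise, history and contrast biases, reward-history
#' terms and lapse mixing:
#'
#' * `DM1` - single noise SD, side bias `beta0`, previous-choice bias
#'   `beta1`, symmetric lapse `lambda`;
#' * `DM2` - one noise SD per contrast level;
#' * `DM3` - adds the contrast-difference bias `beta2 * (c_l - c_r)`;
#' * `DM4` - DM3 with separate left/right lapse rates;
#' * `DM5` - DM3 plus a reward-history term `beta3 * (D * R)` from the
#'   previous trial;
#' * `DM6` - DM4 and DM5 combined.
#'
#' @param model One of `"DM1"` ... `"DM6"`.
#' @param sigma Noise SD in verticality degrees: a single value for DM1,
#'   or one value per contrast level (named by contrast, or in the order
#'   of `contrasts`) for DM2+.
#' @param beta0,beta1,beta2,beta3 Bias weights (only the ones the model
#'   uses are consulted).
#' @param lapse Symmetric lapse rate in `[0, 1]` (models with one lapse).
#' @param lapse_left,lapse_right Side-specific lapse rates (DM4/DM6); the
#'   mixture is `Phi(z) * (1 - l_L - l_R) + l_L`, so each is that side's
#'   stimulus-independent guess rate.
#' @param contrasts Contrast levels to which a vector `sigma` refers.
#' @return A list of class `ri_dm`.
#' @export
dm_params <- function(model = c("DM1", "DM2", "DM3", "DM4", "DM5", "DM6"),
                      sigma, beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                      lapse = 0, lapse_left = 0, lapse_right = 0,
                      contrasts = task_contrasts()) {
  model <- match.arg(model)
  if (any(sigma <= 0)) stop("`sigma` must be positive.", call. = FALSE)
  if (model == "DM1") {
    if (length(sigma) != 1) stop("DM1 uses a single `sigma`.", call. = FALSE)
  } else {
    if (length(sigma) != length(contrasts)) {
      stop("DM2+ need one `sigma` per contrast level.", call. = FALSE)
    }
    if (is.null(names(sigma))) names(sigma) <- as.character(contrasts)
  }
  lam <- c(lapse, lapse_left, lapse_right)
  if (any(lam < 0) || any(lam > 1) || lapse_left + lapse_right > 1) {
    stop("lapse rates must lie in [0, 1] (and sum to at most 1).", call. = FALSE)
  }
  structure(list(
    model = model, sigma = sigma,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
    lapse = lapse, lapse_left = lapse_left, lapse_right = lapse_right,
    contrasts = contrasts
  ), class = "ri_dm")
}

.dm_sigma_of <- function(params, contrast) {
  if (params$model == "DM1") {
    rep_len(params$sigma, length(contrast))
  } else {
    unname(params$sigma[as.character(contrast)])
  }
}

#' Number of free parameters of a descriptive model
#' @param model Model id `"DM1"` ... `"DM6"`.
#' @param n_contrasts Number of contrast levels (noise SDs in DM2+).
#' @return Integer parameter count.
#' @export
dm_n_params <- function(model, n_contrasts = 3) {
  switch(model,
    DM1 = 4L,                         # sigma, beta0, beta1, lambda
    DM2 = n_contrasts + 3L,
    DM3 = n_contrasts + 4L,
    DM4 = n_contrasts + 5L,           # two lapse rates
    DM5 = n_contrasts + 5L,           # beta3
    DM6 = n_contrasts + 6L,
    stop("unknown model id.", call. = FALSE)
  )
}

#' Descriptive model choice probability
#'
#' Probability of choosing the left grating under a descriptive probit
#' model. The angle difference is taken in verticality space. DM5/DM6
#' require `prev_choice` and `prev_reward` columns; all models use
#' `prev_choice` for the history bias when present (D = +1 after left,
#' -1 after right, 0 on first trials).
#'
#' @param trials Trial table with `theta_l`, `theta_r`, `c_l`, `c_r` and
#'   any history columns the model needs.
#' @param params An [dm_params()] object.
#' @return The input tibble with a `p_left` column appended. Values lie
#'   strictly inside `[lambda/2, 1 - lambda/2]` (or the side-specific
#'   analogue).
#' @export
dm_choice_probability <- function(trials, params) {
  stopifnot(inherits(params, "ri_dm"))
  model <- params$model
  dv <- verticality(trials$theta_l) - verticality(trials$theta_r)
  sl <- .dm_sigma_of(params, trials$c_l)
  sr <- .dm_sigma_of(params, trials$c_r)
  if (any(is.na(sl)) || any(is.na(sr))) {
    stop("trial contrasts outside the model's contrast set.", call. = FALSE)
  }
  s <- if (model == "DM1") params$sigma * sqrt(2) else sqrt(sl^2 + sr^2)
  D <- if ("prev_choice" %in% names(trials)) .prev_D(trials$prev_choice) else 0
  z <- dv / s + params$beta0 + params$beta1 * D
  if (model %in% c("DM3", "DM4", "DM5", "DM6")) {
    z <- z + params$beta2 * (trials$c_l - trials$c_r)
  }
  if (model %in% c("DM5", "DM6")) {
    if (!all(c("prev_choice", "prev_reward") %in% names(trials))) {
      stop("DM5/DM6 need `prev_choice` and `prev_reward` columns.", call. = FALSE)
    }
    pr <- trials$prev_reward
    pr[is.na(pr)] <- 0
    z <- z + params$beta3 * D * pr
  }
  phi <- stats::pnorm(z)
  p <- if (model %in% c("DM4", "DM6")) {
    phi * (1 - params$lapse_left - params$lapse_right) + params$lapse_left
  } else {
    phi * (1 - params$lapse) + params$lapse / 2
  }
  dplyr::mutate(tibble::as_tibble(trials), p_left = p)
}
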