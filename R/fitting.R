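#' Negative log-likelihood of a choice model on a trial table
#'
#' Sums `-log p(choice)` over non-excluded trials, with per-trial choice
#' probabilities from the descriptive model ([dm_choice_probability()]) or
#' the rational-inattention observer ([choice_probability()]).
#' Probabilities are clipped to `[1e-9, 1 - 1e-9]` so the result is
#' finite.
#'
#' @param trials Trial table with a `choice` column.
#' @param params An `ri_dm` or `ri_observer` object.
#' @param prior Orientation prior (required for observer models).
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(trials, params, prior = NULL) {
  if (!nrow(trials)) stop("empty trial table.", call. = FALSE)
  if (!"choice" %in% names(trials)) {
    stop("`trials` must contain a `choice` column.", call. = FALSE)
  }
  if ("excluded" %in% names(trials)) {
    trials <- trials[!trials$excluded, ]
  }
  p <- if (inherits(params, "ri_dm")) {
    dm_choice_probability(trials, params)$p_left
  } else if (inherits(params, "ri_observer")) {
    if (is.null(prior)) stop("observer models need `prior`.", call. = FALSE)
    choice_probability(trials, params, prior)$p_left
  } else {
    stop("`params` must be an ri_dm or ri_observer object.", call. = FALSE)
  }
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(ifelse(trials$choice == "left", log(p), log(1 - p)))
}

.fit_result <- function(model_id, estimates, params, nll, trials, n_params,
                        diagnostics, seed, extra = list()) {
  n <- sum(if ("excluded" %in% names(trials)) !trials$excluded else rep(TRUE, nrow(trials)))
  structure(c(list(
    model_id = model_id,
    estimates = estimates,
    params = params,
    logLik = -nll,
    AIC = 2 * n_params + 2 * nll,
    BIC = n_params * log(n) + 2 * nll,
    n_trials = n,
    n_params = n_params,
    diagnostics = diagnostics,
    seed = seed,
    data_checksum = .data_checksum(trials)
  ), extra), class = "ri_fit")
}

.data_checksum <- function(trials) {
  keep <- if ("excluded" %in% names(trials)) !trials$excluded else TRUE
  t2 <- trials[keep, ]
  sum(t2$theta_l + 2 * t2$theta_r + 100 * t2$c_l) +
    sum(t2$choice == "left") * pi
}

.multi_start <- function(objective, draw_start, starts, seed, maxit = 500) {
  start_list <- withr::with_seed(seed, replicate(starts, draw_start(),
    simplify = FALSE
  ))
  fits <- lapply(start_list, function(p0) {
    tryCatch(
      stats::optim(p0, objective,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-8)
      ),
      error = function(e) list(par = p0, value = Inf, convergence = 99L)
    )
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(!is.finite(vals))) {
    stop("all optimization starts failed.", call. = FALSE)
  }
  list(
    best = fits[[which.min(vals)]],
    diagnostics = tibble::tibble(
      start = seq_along(fits), value = vals,
      convergence = vapply(fits, function(f) as.integer(f$convergence), integer(1))
    )
  )
}

# ---- descriptive model fitting ------------------------------------------

.dm_pack_info <- function(model, contrasts) {
  ns <- if (model == "DM1") 1L else length(contrasts)
  nm <- c(
    paste0("log_sigma", seq_len(ns)),
    "beta0", "beta1",
    if (model %in% c("DM3", "DM4", "DM5", "DM6")) "beta2",
    if (model %in% c("DM5", "DM6")) "beta3",
    if (model %in% c("DM4", "DM6")) c("lg_lapse_l", "lg_lapse_r") else "lg_lapse"
  )
  list(ns = ns, names = nm, n = length(nm))
}

.dm_unpack <- function(par, model, contrasts) {
  info <- .dm_pack_info(model, contrasts)
  p <- stats::setNames(par, info$names)
  sigma <- exp(p[seq_len(info$ns)])
  if (model != "DM1") names(sigma) <- as.character(contrasts)
  dm_params(
    model = model, sigma = sigma,
    beta0 = p[["beta0"]], beta1 = p[["beta1"]],
    beta2 = if ("beta2" %in% info$names) p[["beta2"]] else 0,
    beta3 = if ("beta3" %in% info$names) p[["beta3"]] else 0,
    lapse = if ("lg_lapse" %in% info$names) stats::plogis(p[["lg_lapse"]]) else 0,
    lapse_left = if ("lg_lapse_l" %in% info$names) 0.5 * stats::plogis(p[["lg_lapse_l"]]) else 0,
    lapse_right = if ("lg_lapse_r" %in% info$names) 0.5 * stats::plogis(p[["lg_lapse_r"]]) else 0,
    contrasts = contrasts
  )
}

#' Fit a descriptive model by multi-start maximum likelihood
#'
#' @param trials Trial table with choices and any history columns the
#'   model needs.
#' @param model Model id `"DM1"` ... `"DM6"`.
#' @param starts Number of random starts.
#' @param seed Seed for the start draws.
#' @param contrasts Contrast levels (noise SDs in DM2+).
#' @return An object of class `ri_fit` (see [tidy.ri_fit()],
#'   [glance.ri_fit()]).
#' @export
fit_dm <- function(trials, model = "DM3", starts = 100, seed = 1,
                   contrasts = task_contrasts()) {
  stopifnot(starts >= 1)
  info <- .dm_pack_info(model, contrasts)
  objective <- function(par) {
    params <- tryCatch(.dm_unpack(par, model, contrasts), error = function(e) NULL)
    if (is.null(params)) {
      return(1e10)
    }
    negative_log_likelihood(trials, params)
  }
  draw_start <- function() {
    c(
      stats::runif(info$ns, log(3), log(30)),
      stats::runif(2, -0.5, 0.5),
      if ("beta2" %in% info$names) stats::runif(1, -1, 1),
      if ("beta3" %in% info$names) stats::runif(1, -0.2, 0.2),
      if ("lg_lapse" %in% info$names) {
        stats::qlogis(stats::runif(1, 0.005, 0.2))
      } else {
        stats::qlogis(stats::runif(2, 0.01, 0.3))
      }
    )
  }
  ms <- .multi_start(objective, draw_start, starts, seed)
  params <- .dm_unpack(ms$best$par, model, contrasts)
  est <- stats::setNames(ms$best$par, info$names)
  .fit_result(model, est, params, ms$best$value, trials,
    dm_n_params(model, length(contrasts)), ms$diagnostics, seed
  )
}

# ---- rational-inattention observer fitting ------------------------------

.obs_from_par <- function(par, variant, prior, env_id = NULL,
                          inner_starts = 4, inner_maxit = 150) {
  step <- attr(prior, "step")
  b0 <- par[1]
  b1 <- par[2]
  b2 <- par[3]
  q <- exp(par[4])
  c50 <- stats::plogis(par[5])
  sigma_late <- exp(par[6])
  if (variant == "g-free") {
    coef <- par[8:10]
    if (!gain_coef_valid(coef)) {
      return(NULL)
    }
    gain <- resource_gain(coef, step = step)
    k_max <- exp(par[7])
  } else if (variant == "g-const") {
    gain <- resource_gain(c(0, 0, 0), step = step)
    k_max <- exp(par[7])
  } else { # g-endog: eta in par[7]; g and k_max from the inner optimizer
    eta <- exp(par[7])
    opt <- optimize_gain(
      reward_environment(env_id), cost_model(eta), sigma_late, prior,
      q = q, c50 = c50, starts = inner_starts, seed = 1, maxit = inner_maxit
    )
    gain <- opt$gain
    k_max <- opt$k_max
  }
  if (k_max <= 0 || k_max > 500 || sigma_late > 200 || q > 20) {
    return(NULL)
  }
  observer_params(gain, contrast_response(k_max, q = q, c50 = c50),
    sigma_late = sigma_late, beta0 = b0, beta1 = b1, beta2 = b2
  )
}

#' Fit the rational-inattention observer to choices
#'
#' Three fit variants of the observer model:
#' * `"g-endog"` fits the cost scale `eta` along with the biases, contrast
#'   response shape and late noise; the gain function and `k_max` are
#'   derived by the internal resource optimizer at every evaluation, so
#'   the model has the same number of free parameters as DM3;
#' * `"g-free"` fits the gain polynomial coefficients and `k_max`
#'   directly (model-free allocation);
#' * `"g-const"` pins the gain at uniform and fits `k_max`.
#'
#' The g-endog variant is expensive (an inner optimization per likelihood
#' evaluation); inner optimizer results are cached on a rounded parameter
#' key within a fit.
#'
#' @param trials Trial table with choices.
#' @param prior An [orientation_prior()] tibble.
#' @param variant `"g-endog"`, `"g-free"` or `"g-const"`.
#' @param starts Number of random starts.
#' @param seed Seed.
#' @param env_id Reward environment (g-endog only); defaults to the
#'   table's `env_id`.
#' @param inner_starts,inner_maxit Inner optimizer effort (g-endog).
#' @param maxit Outer Nelder-Mead iteration cap.
#' @return An `ri_fit` object.
#' @export
fit_observer <- function(trials, prior,
                         variant = c("g-free", "g-const", "g-endog"),
                         starts = 100, seed = 1, env_id = NULL,
                         inner_starts = 4, inner_maxit = 150,
                         maxit = 500) {
  variant <- match.arg(variant)
  if (variant == "g-endog" && is.null(env_id)) {
    env_id <- unique(trials$env_id)
    if (length(env_id) != 1) {
      stop("g-endog needs a single reward environment.", call. = FALSE)
    }
  }
  cache <- new.env(parent = emptyenv())
  objective <- function(par) {
    key <- paste(signif(par, 4), collapse = "_")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    obs <- .obs_from_par(par, variant, prior, env_id, inner_starts, inner_maxit)
    val <- if (is.null(obs)) {
      1e10
    } else {
      negative_log_likelihood(trials, obs, prior)
    }
    cache[[key]] <- val
    val
  }
  draw_start <- function() {
    c(
      stats::runif(3, -0.5, 0.5),            # beta0..beta2
      stats::runif(1, log(1), log(4)),       # log q
      stats::qlogis(stats::runif(1, 0.2, 0.8)), # c50
      stats::runif(1, log(3), log(25)),      # log sigma_late
      if (variant == "g-endog") {
        stats::runif(1, log(1e-4), log(0.3)) # log eta
      } else {
        stats::runif(1, log(5), log(60))     # log k_max
      },
      if (variant == "g-free") {
        repeat {
          coef <- stats::runif(3, -1, 1)
          if (gain_coef_valid(coef)) break
        }
        coef
      }
    )
  }
  ms <- .multi_start(objective, draw_start, starts, seed, maxit = maxit)
  obs <- .obs_from_par(ms$best$par, variant, prior, env_id, inner_starts, inner_maxit)
  n_params <- switch(variant, `g-endog` = 7L, `g-const` = 7L, `g-free` = 10L)
  nm <- c(
    "beta0", "beta1", "beta2", "log_q", "lg_c50", "log_sigma_late",
    if (variant == "g-endog") "log_eta" else "log_k_max",
    if (variant == "g-free") c("g0", "g1", "g2")
  )
  .fit_result(variant, stats::setNames(ms$best$par, nm), obs, ms$best$value,
    trials, n_params, ms$diagnostics, seed,
    extra = list(prior = prior)
  )
}

# ---- model comparison ----------------------------------------------------

#' Compare fitted models by information criteria
#'
#' @param ... `ri_fit` objects fitted to the same trial table.
#' @return A tibble ordered by AIC (ties broken by fewer parameters) with
#'   `dAIC`/`dBIC` relative to the best model.
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "ri_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2) stop("need at least two fits.", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "ri_fit")))
  cks <- vapply(fits, `[[`, numeric(1), "data_checksum")
  if (max(abs(cks - cks[1])) > 1e-6) {
    stop("fits were not computed on the same trial table.", call. = FALSE)
  }
  out <- tibble::tibble(
    model = vapply(fits, `[[`, character(1), "model_id"),
    n_params = vapply(fits, function(f) as.integer(f$n_params), integer(1)),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC")
  )
  out <- dplyr::arrange(out, .data$AIC, .data$n_params)
  dplyr::mutate(out, dAIC = .data$AIC - .data$AIC[1], dBIC = .data$BIC - min(.data$BIC))
}

# ---- covariate-modulated precision --------------------------------------

#' Rescale an observer's sensory and late precision
#'
#' Multiplies the encoding precision (`k_max`, hence `k(c)`) by `s_sens`
#' and the late precision `1/sigma_late^2` by `s_late` (so
#' `sigma_late -> sigma_late / sqrt(s_late)`).
#'
#' @param obs An [observer_params()] object.
#' @param s_sens,s_late Positive multiplicative factors.
#' @return A modified `ri_observer`.
#' @export
modulated_observer <- function(obs, s_sens = 1, s_late = 1) {
  stopifnot(s_sens > 0, s_late > 0)
  observer_params(
    obs$gain,
    contrast_response(obs$cr$k_max * s_sens, q = obs$cr$q, c50 = obs$cr$c50),
    sigma_late = obs$sigma_late / sqrt(s_late),
    beta0 = obs$beta0, beta1 = obs$beta1, beta2 = obs$beta2,
    convention = obs$convention
  )
}

#' Fit per-level sensory and late precision factors
#'
#' Joint maximum-likelihood readout of multiplicative sensory-precision
#' and late-precision factors for each level of a binary covariate (e.g.
#' a high/low arousal split), with all other observer parameters held at
#' `base`.
#'
#' @param trials Trial table with a `choice` column and the covariate
#'   column.
#' @param base An [observer_params()] object (shared parameters).
#' @param prior An [orientation_prior()] tibble.
#' @param covariate Name of the covariate column (two levels).
#' @param starts Number of random starts.
#' @param seed Seed.
#' @return An `ri_fit` whose `estimates` element is a tibble with one row
#'   per level and columns `s_sens`, `s_late`.
#' @export
fit_covariate_modulation <- function(trials, base, prior,
                                     covariate = "covariate",
                                     starts = 8, seed = 1) {
  if (!covariate %in% names(trials)) {
    stop(sprintf("column `%s` not found.", covariate), call. = FALSE)
  }
  levels <- sort(unique(trials[[covariate]]))
  if (length(levels) != 2) {
    stop("the covariate must have exactly two populated levels.", call. = FALSE)
  }
  if ("excluded" %in% names(trials)) trials <- trials[!trials$excluded, ]
  # the base observer carries no history terms, so trials sharing the same
  # stimulus/contrast cell share a choice probability; aggregating cells
  # makes the likelihood cost independent of the trial count
  if (base$beta1 != 0) {
    stop("the covariate fit assumes a history-free base observer.", call. = FALSE)
  }
  subsets <- lapply(levels, function(l) {
    sub <- trials[trials[[covariate]] == l, ]
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$theta_l, .data$theta_r, .data$c_l, .data$c_r),
      n_left = sum(.data$choice == "left"), n = dplyr::n(), .groups = "drop"
    )
    agg
  })
  agg_nll <- function(agg, obs) {
    p <- choice_probability(agg, obs, prior)$p_left
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(agg$n_left * log(p) + (agg$n - agg$n_left) * log(1 - p))
  }
  objective <- function(par) {
    s <- exp(par)
    if (any(s < 0.05) || any(s > 20)) {
      return(1e10)
    }
    nll <- 0
    for (k in 1:2) {
      obs_k <- modulated_observer(base, s_sens = s[k], s_late = s[k + 2])
      nll <- nll + agg_nll(subsets[[k]], obs_k)
    }
    nll
  }
  draw_start <- function() stats::runif(4, log(0.5), log(2))
  ms <- .multi_start(objective, draw_start, starts, seed, maxit = 400)
  s <- exp(ms$best$par)
  est <- tibble::tibble(
    level = levels, s_sens = s[1:2], s_late = s[3:4]
  )
  .fit_result("precision-modulation", est, base, ms$best$value, trials,
    4L, ms$diagnostics, seed,
    extra = list(prior = prior)
  )
}

# ---- bootstrap -----------------------------------------------------------

#' Percentile bootstrap confidence interval
#'
#' @param data Vector or data frame (resampled by element / by row).
#' @param statistic Function of a resample returning a scalar.
#' @param reps Number of bootstrap replicates (>= 100).
#' @param seed Seed.
#' @param level Confidence level.
#' @return A tibble with `estimate`, `lower`, `upper`, `reps_used`.
#'   Degenerate (non-finite) replicates are dropped with a warning.
#' @export
bootstrap_ci <- function(data, statistic, reps = 1000, seed = 1, level = 0.95) {
  stopifnot(reps >= 100)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  draw <- function() {
    idx <- sample.int(n, n, replace = TRUE)
    if (is.data.frame(data)) statistic(data[idx, , drop = FALSE]) else statistic(data[idx])
  }
  stats_v <- withr::with_seed(seed, replicate(reps, draw()))
  ok <- is.finite(stats_v)
  if (!all(ok)) {
    warning(sprintf("%d degenerate bootstrap replicates excluded.", sum(!ok)))
  }
  qs <- stats::quantile(stats_v[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
    names = FALSE
  )
  tibble::tibble(
    estimate = statistic(data), lower = qs[1], upper = qs[2],
    reps_used = sum(ok)
  )
}
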