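#' Cost model for encoding precision
#'
#' The metabolic cost charged against reward in the resource-allocation
#' objective. `"precision"` charges `eta` per unit of prior-averaged
#' encoding precision (the default, motivated by the near-linear relation
#' between neural activity and energy use); `"mutual_information"` charges
#' `eta` per nat of expected uncertainty reduction, the classical rational
#' inattention cost.
#'
#' @param eta Non-negative cost scale (per precision unit, or per nat).
#' @param kind `"precision"` or `"mutual_information"`.
#' @return A list of class `ri_cost`.
#' @export
cost_model <- function(eta, kind = c("precision", "mutual_information")) {
  stopifnot(eta >= 0)
  structure(list(eta = eta, kind = match.arg(kind)), class = "ri_cost")
}

#' Prior-averaged encoding precision
#'
#' Mean over the contrast set of the prior-weighted average precision
#' `integral pi(theta) g(theta) k(c) dtheta`.
#'
#' @param obs An [observer_params()] object.
#' @param prior An [orientation_prior()] tibble.
#' @param contrasts Contrast set (default the task's three levels).
#' @return Scalar average precision (von Mises concentration units).
#' @export
average_precision <- function(obs, prior, contrasts = task_contrasts()) {
  stopifnot(inherits(obs, "ri_observer"), length(contrasts) >= 1)
  mean(k_of_contrast(obs$cr, contrasts)) * sum(prior$density * obs$gain$g)
}

#' Mutual information between stimulus and measurement
#'
#' Expected reduction in uncertainty about the stimulus after observing a
#' measurement, `I(theta; m) = H(theta) - E[H(theta | m)]`, computed on the
#' discrete grid and averaged over the contrast set. Non-negative.
#'
#' @inheritParams average_precision
#' @return Mutual information in nats.
#' @export
mutual_information_cost <- function(obs, prior, contrasts = task_contrasts()) {
  stopifnot(inherits(obs, "ri_observer"))
  mis <- vapply(contrasts, function(cc) {
    P <- .measurement_rows(k_of_contrast(obs$cr, cc) * obs$gain$g,
      attr(prior, "step"))
    .grid_mi(P, prior$density)
  }, numeric(1))
  mi <- mean(mis)
  if (mi < -1e-8) stop("negative mutual information beyond tolerance.", call. = FALSE)
  max(mi, 0)
}

.grid_mi <- function(P, prior_density) {
  joint <- P * prior_density            # rows: theta, cols: m
  pm <- colSums(joint)
  hx <- -sum(prior_density * log(pmax(prior_density, 1e-300)))
  # E[H(theta | m)] = -sum_m p(m) sum_theta p(theta|m) log p(theta|m)
  post <- sweep(joint, 2, pmax(pm, 1e-300), `/`)
  hcond <- -colSums(post * log(pmax(post, 1e-300)))
  hx - sum(pm * hcond)
}

#' Default task difficulty set
#'
#' Verticality differences (degrees) between the two gratings used in the
#' task: 20 to 90 in steps of 10.
#' @return Numeric vector.
#' @export
task_difficulties <- function() seq(20, 90, by = 10)

# Masked stimulus pairs (grid indices) whose verticality difference lies in
# the difficulty set, with the weight each ordered pair receives under the
# task's generative procedure: the correct-side orientation is drawn from
# the prior (restricted to orientations that admit at least one
# difficulty), the difficulty uniformly from the feasible subset of the
# set, and the less-vertical stimulus is placed at either preimage of the
# target verticality with equal probability. `"prior-product"` weights
# pairs by independent prior draws instead (the continuous double-integral
# reading). Memoized per grid/difficulty set.
.pair_mask <- function(prior, difficulties, weighting = "task") {
  step <- attr(prior, "step")
  key <- paste0(
    "pairs_", step, "_", weighting, "_",
    paste(difficulties, collapse = ".")
  )
  if (is.null(.ri_cache[[key]])) {
    theta <- prior$theta
    v <- verticality(theta)
    if (weighting == "dense") {
      # full double integral over independent prior draws, all pairs
      n <- length(theta)
      idx <- expand.grid(i = seq_len(n), j = seq_len(n))
      i <- idx$i
      j <- idx$j
      w <- prior$density[i] * prior$density[j]
    } else if (weighting == "prior-product") {
      dv <- abs(outer(v, v, `-`))
      keep <- which(matrix(round(dv, 6) %in% difficulties, nrow = nrow(dv)),
        arr.ind = TRUE
      )
      w <- prior$density[keep[, 1]] * prior$density[keep[, 2]]
      i <- keep[, 1]
      j <- keep[, 2]
    } else {
      i <- j <- w <- numeric(0)
      for (ic in seq_along(theta)) {
        feas <- difficulties[difficulties <= v[ic]]
        if (!length(feas)) next
        for (d in feas) {
          vo <- v[ic] - d
          pre <- unique(c(vo, (180 - vo) %% 180))
          io <- match(round(pre, 6), round(theta, 6))
          io <- io[!is.na(io)]
          ww <- prior$density[ic] / length(feas) / length(io)
          i <- c(i, rep(ic, length(io)))
          j <- c(j, io)
          w <- c(w, rep(ww, length(io)))
        }
      }
      # randomize sides: split each (correct, other) pair over both orders
      i2 <- c(i, j)
      j2 <- c(j, i)
      w2 <- c(w, w) / 2
      i <- i2
      j <- j2
      w <- w2
    }

    .ri_cache[[key]] <- list(
      i = i, j = j, w = w / sum(w),
      v_i = v[i], v_j = v[j]
    )
  }
  .ri_cache[[key]]
}

# reward carried by the correct (more vertical) side for each masked pair
.pair_reward <- function(env, mask) {
  r_i <- env$reward_fun(mask$v_i)
  r_j <- env$reward_fun(mask$v_j)
  switch(env$env_id,
    constant = rep(5, length(r_i)),
    increasing = pmax(r_i, r_j),
    decreasing = pmin(r_i, r_j)
  )
}

# loss/reward accounting over the masked pair distribution for one set of
# per-contrast moment tables
.pair_accounting <- function(tabs, contrasts, sigma_late, mask, rw) {
  loss <- reward <- 0
  nc <- length(contrasts)
  for (a in seq_len(nc)) {
    ta <- tabs[[as.character(contrasts[a])]]
    for (b in seq_len(nc)) {
      tb <- tabs[[as.character(contrasts[b])]]
      dz <- abs(ta$mean_v[mask$i] - tb$mean_v[mask$j]) /
        sqrt(ta$var_v[mask$i] + tb$var_v[mask$j] + sigma_late^2)
      perr <- stats::pnorm(-dz)
      loss <- loss + sum(mask$w * rw * perr)
      reward <- reward + sum(mask$w * rw * (1 - perr))
    }
  }
  c(loss = loss / nc^2, reward = reward / nc^2)
}

#' Expected reward loss of an observer in an environment
#'
#' Reward-weighted expected error probability per trial, averaged over the
#' contrast-pair product (equal weights) and over stimulus pairs drawn
#' from the prior restricted to the task's discrete difficulty set. In the
#' constant environment every error forfeits the fixed 5 ul; in the
#' increasing environment the forfeited reward is the larger of the two
#' stimulus rewards (the correct, more vertical side carries it), and in
#' the decreasing environment the smaller.
#'
#' @param env An [reward_environment()] object.
#' @param obs An [observer_params()] object.
#' @param prior An [orientation_prior()] tibble.
#' @param contrasts Contrast set.
#' @param difficulties Verticality-difference set defining the stimulus
#'   pairs integrated over.
#' @param weighting Stimulus-pair weighting: `"task"` (the generative
#'   distribution of the task) or `"prior-product"` (independent prior
#'   draws restricted to the difficulty set).
#' @return Expected loss in microlitres per trial.
#' @export
expected_loss <- function(env, obs, prior, contrasts = task_contrasts(),
                          difficulties = task_difficulties(),
                          weighting = c("task", "prior-product", "dense")) {
  weighting <- match.arg(weighting)
  .expected_accounting(env, obs, prior, contrasts, difficulties, weighting)[["loss"]]
}

#' Expected reward per trial
#'
#' Complement of [expected_loss()]: reward-weighted expected probability
#' of a correct choice under the same stimulus/contrast distribution.
#'
#' @inheritParams expected_loss
#' @return Expected reward in microlitres per trial.
#' @export
expected_reward <- function(env, obs, prior, contrasts = task_contrasts(),
                            difficulties = task_difficulties(),
                            weighting = c("task", "prior-product", "dense")) {
  weighting <- match.arg(weighting)
  .expected_accounting(env, obs, prior, contrasts, difficulties, weighting)[["reward"]]
}

.expected_accounting <- function(env, obs, prior, contrasts, difficulties,
                                 weighting = "task") {
  stopifnot(inherits(env, "ri_env"), inherits(obs, "ri_observer"))
  mask <- .pair_mask(prior, difficulties, weighting)
  rw <- .pair_reward(env, mask)
  tabs <- .observer_tables(obs, prior, contrasts)
  .pair_accounting(tabs, contrasts, obs$sigma_late, mask, rw)
}

#' Optimize the resource gain function for an environment
#'
#' Finds the gain polynomial coefficients and peak precision `k_max` that
#' minimize expected reward loss plus the precision (or mutual
#' information) cost, by derivative-free multi-start search (Nelder-Mead,
#' `k_max` log-parametrized, invalid gain coefficients rejected by
#' penalty).
#'
#' @param env An [reward_environment()] object.
#' @param cost A [cost_model()] object.
#' @param sigma_late Late-noise SD in verticality degrees.
#' @param prior An [orientation_prior()] tibble.
#' @param contrasts Contrast set.
#' @param q,c50 Contrast response shape parameters (held fixed).
#' @param starts Number of random starts (>= 1). The first start is always
#'   the uniform allocation.
#' @param seed Integer seed for the start draws.
#' @param difficulties Stimulus-pair difficulty set.
#' @param k_max_range Search range for `k_max`.
#' @param order Polynomial order p of the gain family (p + 1 coefficients).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param weighting Stimulus-pair weighting: `"task"` (the generative
#'   distribution of the task: correct side from the prior, difficulty
#'   uniform) or `"prior-product"` (independent prior draws restricted to
#'   the difficulty set).
#' @return A list of class `ri_opt` with elements `gain` (an `ri_gain`),
#'   `k_max`, `objective`, `loss`, `cost`, `expected_reward`, `env_id`,
#'   `settings`, and a `diagnostics` tibble (one row per start).
#' @export
optimize_gain <- function(env, cost, sigma_late, prior,
                          contrasts = task_contrasts(),
                          q = 2, c50 = 0.5,
                          starts = 50, seed = 1,
                          difficulties = task_difficulties(),
                          k_max_range = c(3, 150),
                          order = 2, maxit = 400,
                          weighting = c("dense", "task", "prior-product")) {
  stopifnot(inherits(env, "ri_env"), inherits(cost, "ri_cost"), starts >= 1)
  weighting <- match.arg(weighting)
  step <- attr(prior, "step")
  mask <- .pair_mask(prior, difficulties, weighting)
  rw <- .pair_reward(env, mask)
  half_x <- orientation_grid(step)
  half_x <- half_x[half_x < 90] / 90
  dens <- prior$density
  kfrac <- {
    cq <- contrasts^q
    cq / (cq + c50^q)
  }

  objective <- function(par) {
    coef <- par[seq_len(order + 1)]
    if (!gain_coef_valid(coef)) {
      return(1e6 + sum(coef^2))
    }
    k_max <- exp(par[order + 2])
    # hard bounds: below the floor the Gaussian decision-stage
    # approximation is unreliable (see the methods vignette)
    if (k_max < k_max_range[1] || k_max > k_max_range[2]) {
      return(1e6 + abs(par[order + 2]))
    }
    gh <- .gain_deriv(half_x, coef)
    g <- c(gh, rev(gh))
    g <- g / mean(g)
    tabs <- stats::setNames(lapply(seq_along(contrasts), function(ii) {
      .contrast_table(k_max * kfrac[ii] * g, prior, "verticality")
    }), as.character(contrasts))
    acc <- .pair_accounting(tabs, contrasts, sigma_late, mask, rw)
    kbar_or_mi <- if (cost$kind == "precision") {
      mean(k_max * kfrac) * sum(dens * g)
    } else {
      mean(vapply(tabs, function(tt) .grid_mi(tt$P, dens), numeric(1)))
    }
    acc[["loss"]] + cost$eta * kbar_or_mi
  }

  start_pars <- withr::with_seed(seed, {
    sp <- replicate(starts - 1, {
      repeat {
        coef <- stats::runif(order + 1, -1.2, 1.2)
        if (gain_coef_valid(coef)) break
      }
      c(coef, stats::runif(1, log(k_max_range[1]), log(k_max_range[2])))
    }, simplify = FALSE)
    c(list(c(rep(0, order + 1), mean(log(k_max_range)))), sp)
  })

  fits <- lapply(start_pars, function(p0) {
    stats::optim(p0, objective,
      method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-8)
    )
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  coef <- best$par[seq_len(order + 1)]
  k_max <- exp(best$par[order + 2])

  gain <- resource_gain(coef, step = step)
  cr <- contrast_response(k_max, q = q, c50 = c50)
  obs <- observer_params(gain, cr, sigma_late = sigma_late)
  acc <- .expected_accounting(env, obs, prior, contrasts, difficulties, weighting)
  cost_val <- if (cost$kind == "precision") {
    average_precision(obs, prior, contrasts)
  } else {
    mutual_information_cost(obs, prior, contrasts)
  }
  structure(list(
    gain = gain, k_max = k_max,
    objective = best$value,
    loss = acc[["loss"]],
    cost = cost$eta * cost_val,
    expected_reward = acc[["reward"]],
    env_id = env$env_id,
    settings = list(
      eta = cost$eta, cost_kind = cost$kind, sigma_late = sigma_late,
      q = q, c50 = c50, contrasts = contrasts, difficulties = difficulties,
      starts = starts, seed = seed, weighting = weighting
    ),
    diagnostics = tibble::tibble(
      start = seq_along(fits),
      value = vals,
      convergence = vapply(fits, `[[`, numeric(1), "convergence")
    )
  ), class = "ri_opt")
}

#' Observer implied by an optimization result
#'
#' @param opt An `ri_opt` object from [optimize_gain()].
#' @param sigma_late Late-noise SD; defaults to the value used during
#'   optimization.
#' @return An [observer_params()] object.
#' @export
observer_from_opt <- function(opt, sigma_late = opt$settings$sigma_late) {
  observer_params(
    opt$gain,
    contrast_response(opt$k_max, q = opt$settings$q, c50 = opt$settings$c50),
    sigma_late = sigma_late
  )
}

#' Percent reward lost when optimal allocations are swapped
#'
#' Optimizes the gain separately for two environments, then evaluates the
#' expected per-trial reward in environment `a` under its own optimum and
#' under environment `b`'s optimum. The returned value is
#' `100 * (E[R | own] - E[R | swapped]) / E[R | own]`.
#'
#' @param env_a,env_b [reward_environment()] objects.
#' @param cost A [cost_model()] object.
#' @param sigma_late Late-noise SD.
#' @param prior An [orientation_prior()] tibble.
#' @param contrasts Contrast set.
#' @param ... Passed on to [optimize_gain()] (`starts`, `seed`, ...).
#' @param opt_a,opt_b Optional precomputed `ri_opt` results (skips the
#'   optimizations).
#' @return A one-row tibble with the own/swapped expected rewards and the
#'   percent loss.
#' @export
reward_loss_on_swap <- function(env_a, env_b, cost, sigma_late, prior,
                                contrasts = task_contrasts(), ...,
                                opt_a = NULL, opt_b = NULL) {
  if (is.null(opt_a)) {
    opt_a <- optimize_gain(env_a, cost, sigma_late, prior, contrasts, ...)
  }
  if (is.null(opt_b)) {
    opt_b <- optimize_gain(env_b, cost, sigma_late, prior, contrasts, ...)
  }
  own <- expected_reward(env_a, observer_from_opt(opt_a, sigma_late), prior, contrasts)
  swapped <- expected_reward(env_a, observer_from_opt(opt_b, sigma_late), prior, contrasts)
  tibble::tibble(
    env = env_a$env_id, swapped_from = env_b$env_id,
    reward_own = own, reward_swapped = swapped,
    percent_loss = 100 * (own - swapped) / own
  )
}
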