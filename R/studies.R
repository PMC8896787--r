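#' Expected accuracy of an observer on the task
#'
#' Probability of a correct choice averaged over the task's stimulus-pair
#' and contrast distribution (unweighted by reward).
#'
#' @inheritParams expected_loss
#' @return Scalar expected accuracy in `[0.5, 1]`.
#' @export
expected_accuracy <- function(obs, prior, contrasts = task_contrasts(),
                              difficulties = task_difficulties()) {
  mask <- .pair_mask(prior, difficulties)
  tabs <- .observer_tables(obs, prior, contrasts)
  acc <- .pair_accounting(
    tabs, contrasts, obs$sigma_late, mask,
    rep(1, length(mask$i))
  )
  acc[["reward"]]
}

#' Reference task settings
#'
#' The package's standard operating point for simulation studies:
#' contrast response shape, late noise and precision cost chosen once so
#' that the endogenously optimized observer performs in the mouse-like
#' 70-80% overall accuracy band on the task's stimulus distribution (see
#' the methods vignette for the calibration procedure).
#'
#' @return A named list with `eta`, `sigma_late`, `q`, `c50`.
#' @export
reference_settings <- function() {
  list(eta = 0.16, sigma_late = 12, q = 2, c50 = 0.5)
}

#' Parameter-recovery study for covariate-modulated precision
#'
#' Simulates datasets from the observer with known per-covariate-level
#' sensory-precision and late-precision factors drawn from a plausible
#' range, refits each dataset by multi-start maximum likelihood
#' ([fit_covariate_modulation()]), and summarizes recovery by the
#' coefficient of determination about the identity line over all pooled
#' recovered-versus-true factor pairs.
#'
#' @param n_datasets Number of simulated datasets (>= 1).
#' @param n_trials Trials per dataset.
#' @param seed Master seed; per-dataset seeds are derived from it.
#' @param scale_range Range the true factors are drawn from.
#' @param starts Multi-start count per fit.
#' @param k_max,sigma_late Base observer operating point. The defaults
#'   (10, 28) minimize the worst-case joint (profile) uncertainty about
#'   the two factors over the factor range; the factors are strongly
#'   correlated in the likelihood, which also sets the trial count
#'   needed per dataset (see the methods vignette).
#' @param prior An [orientation_prior()] tibble.
#' @return A list of class `ri_recovery` with `pairs` (tibble of true
#'   and recovered factors) and `r_squared`.
#' @export
recovery_study <- function(n_datasets = 20, n_trials = 150000, seed = 1,
                           scale_range = c(0.5, 2), starts = 6,
                           k_max = 10, sigma_late = 28,
                           prior = orientation_prior()) {
  stopifnot(n_datasets >= 1, n_trials >= 2)
  base <- observer_params(
    resource_gain(c(0, 0, 0), step = attr(prior, "step")),
    contrast_response(k_max, q = 2, c50 = 0.5),
    sigma_late = sigma_late
  )
  one <- function(d) {
    sd_d <- (seed * 1000L + d) %% .Machine$integer.max
    truth <- withr::with_seed(sd_d, stats::runif(4, scale_range[1], scale_range[2]))
    spec <- session_spec(
      n_trials = n_trials, env_id = "constant", truth = base,
      prior = prior, seed = sd_d + 1L
    )
    trials <- generate_trials(spec)
    cov <- withr::with_seed(
      sd_d + 2L,
      sample(c("low", "high"), n_trials, replace = TRUE)
    )
    trials$covariate <- cov
    lev <- sort(unique(cov)) # "high", "low"
    sim <- lapply(seq_along(lev), function(k) {
      sub <- trials[cov == lev[k], ]
      obs_k <- modulated_observer(base, s_sens = truth[k], s_late = truth[k + 2])
      sp <- spec
      sp$truth <- obs_k
      sp$seed <- sd_d + 2L + k
      p <- choice_probability(sub, obs_k, prior)$p_left
      withr::with_seed(sp$seed, {
        sub$choice <- ifelse(stats::runif(nrow(sub)) < p, "left", "right")
      })
      sub
    })
    simtab <- dplyr::arrange(dplyr::bind_rows(sim), .data$trial)
    fit <- fit_covariate_modulation(simtab, base, prior,
      starts = starts, seed = sd_d + 9L
    )
    est <- fit$estimates
    tibble::tibble(
      dataset = d,
      parameter = rep(c("s_sens", "s_late"), each = 2),
      level = rep(est$level, 2),
      truth = truth,
      recovered = c(est$s_sens, est$s_late)
    )
  }
  pairs <- dplyr::bind_rows(lapply(seq_len(n_datasets), one))
  ss_res <- sum((pairs$recovered - pairs$truth)^2)
  ss_tot <- sum((pairs$truth - mean(pairs$truth))^2)
  structure(list(
    pairs = pairs,
    r_squared = 1 - ss_res / ss_tot,
    n_datasets = n_datasets, n_trials = n_trials, seed = seed
  ), class = "ri_recovery")
}

#' Reward-loss-on-swap study for the linear environments
#'
#' Optimizes the resource allocation separately for the increasing and
#' decreasing reward environments at the reference (mouse-like accuracy)
#' settings, cross-evaluates each environment under the other's optimum,
#' and reports the percent reward loss in each direction and their mean.
#'
#' @param seed Seed for the optimizer starts.
#' @param starts Multi-start count per optimization.
#' @param settings Task settings (see [reference_settings()]).
#' @param prior An [orientation_prior()] tibble.
#' @return A list of class `ri_swap` with the two `ri_opt` results, a
#'   `losses` tibble (one row per direction), `mean_percent_loss`, and
#'   the optimized observers' expected accuracies.
#' @export
swap_study <- function(seed = 1, starts = 16,
                       settings = reference_settings(),
                       prior = orientation_prior()) {
  cost <- cost_model(settings$eta, "precision")
  env_inc <- reward_environment("increasing")
  env_dec <- reward_environment("decreasing")
  opt_inc <- optimize_gain(env_inc, cost, settings$sigma_late, prior,
    q = settings$q, c50 = settings$c50, starts = starts, seed = seed
  )
  opt_dec <- optimize_gain(env_dec, cost, settings$sigma_late, prior,
    q = settings$q, c50 = settings$c50, starts = starts, seed = seed + 1L
  )
  l1 <- reward_loss_on_swap(env_inc, env_dec, cost, settings$sigma_late, prior,
    opt_a = opt_inc, opt_b = opt_dec
  )
  l2 <- reward_loss_on_swap(env_dec, env_inc, cost, settings$sigma_late, prior,
    opt_a = opt_dec, opt_b = opt_inc
  )
  losses <- dplyr::bind_rows(l1, l2)
  acc <- c(
    increasing = expected_accuracy(observer_from_opt(opt_inc), prior),
    decreasing = expected_accuracy(observer_from_opt(opt_dec), prior)
  )
  structure(list(
    opt_increasing = opt_inc, opt_decreasing = opt_dec,
    losses = losses,
    mean_percent_loss = mean(losses$percent_loss),
    accuracy = acc, seed = seed
  ), class = "ri_swap")
}

#' Closed-loop learning versus the static optimum
#'
#' Runs the reinforcement-learning allocator in one environment with the
#' contrast response and late noise of that environment's static
#' optimum, and compares the time-averaged learned gain (last `window`
#' trials) against the static optimal gain by Spearman rank correlation.
#'
#' @param env_id Environment id.
#' @param n_trials Closed-loop trials.
#' @param window Trailing window for the time average.
#' @param seed Seed.
#' @param starts Static-optimizer starts.
#' @param rl An [rl_params()] object.
#' @param settings Task settings.
#' @param prior An [orientation_prior()] tibble.
#' @param opt Optional precomputed static `ri_opt` for `env_id`.
#' @return A list of class `ri_rl_study` with the static `opt`, the
#'   `run`, the averaged gain and `spearman`.
#' @export
rl_convergence_study <- function(env_id = "increasing", n_trials = 1500,
                                 window = 500, seed = 1, starts = 30,
                                 rl = rl_params(),
                                 settings = reference_settings(),
                                 prior = orientation_prior(),
                                 opt = NULL) {
  if (is.null(opt)) {
    opt <- optimize_gain(
      reward_environment(env_id), cost_model(settings$eta),
      settings$sigma_late, prior,
      q = settings$q, c50 = settings$c50,
      starts = starts, seed = seed
    )
  }
  obs <- observer_from_opt(opt)
  spec <- session_spec(
    n_trials = n_trials, env_id = env_id, prior = prior,
    seed = (seed * 7L + 3L) %% .Machine$integer.max
  )
  trials <- generate_trials(spec)
  run <- run_rl_session(trials, obs, prior,
    params = rl,
    seed = (seed * 11L + 5L) %% .Machine$integer.max
  )
  g_bar <- mean_gain(run, window)
  rho <- stats::cor(g_bar$g, opt$gain$g, method = "spearman")
  structure(list(
    env_id = env_id, opt = opt, run = run, mean_gain = g_bar,
    spearman = rho, seed = seed
  ), class = "ri_rl_study")
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate -> fit -> optimize -> learn -> MDS with a single
#' master seed fanned out to every stage, writing CSV/JSON artifacts and
#' a manifest to the output directory. The configuration may be a YAML
#' file path or a named list; missing keys raise an error naming the
#' key.
#'
#' @param config YAML path or list with keys `seed`, `out_dir`, and
#'   optional stage settings (`n_trials`, `env_id`, `dm_model`,
#'   `starts`, `rl_trials`).
#' @return The manifest (named list), invisibly; artifacts are written
#'   to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("seed", "out_dir")) {
    if (is.null(config[[key]])) {
      stop(sprintf("configuration key `%s` is missing.", key), call. = FALSE)
    }
  }
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  n_trials <- config$n_trials %||% 2000
  env_id <- config$env_id %||% "increasing"
  dm_model <- config$dm_model %||% "DM3"
  starts <- config$starts %||% 20
  rl_trials <- config$rl_trials %||% 800
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  prior <- orientation_prior()
  settings <- reference_settings()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  opt <- stage("optimize", optimize_gain(
    reward_environment(env_id), cost_model(settings$eta),
    settings$sigma_late, prior,
    q = settings$q, c50 = settings$c50, starts = starts, seed = seed
  ))
  obs <- observer_from_opt(opt)
  trials <- stage("simulate", simulate_session(session_spec(
    n_trials = n_trials, env_id = env_id, truth = obs,
    prior = prior, seed = seed + 1L
  )))
  write_trials(trials, file.path(out_dir, "trials.csv"))
  fit <- stage("fit", fit_dm(trials, dm_model, starts = starts, seed = seed + 2L))
  run <- stage("learn", rl_convergence_study(
    env_id = env_id, n_trials = rl_trials, seed = seed + 3L,
    settings = settings, prior = prior, opt = opt
  ))
  emb <- stage("mds", mds_embedding(build_dissimilarity(obs, prior)))
  utils::write.csv(as.data.frame(emb), file.path(out_dir, "mds.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    data.frame(theta = opt$gain$theta, g = opt$gain$g),
    file.path(out_dir, "optimal_gain.csv"),
    row.names = FALSE
  )
  fit_json <- list(
    model = fit$model_id, logLik = fit$logLik, AIC = fit$AIC, BIC = fit$BIC,
    estimates = as.list(fit$estimates)
  )
  jsonlite::write_json(fit_json, file.path(out_dir, "dm_fit.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    package = "rattention",
    version = as.character(utils::packageVersion("rattention")),
    seed = seed,
    stages = c("optimize", "simulate", "fit", "learn", "mds"),
    env_id = env_id, n_trials = n_trials, dm_model = dm_model,
    rl_spearman = run$spearman,
    objective = opt$objective,
    fit_logLik = fit$logLik
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
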