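#' Session specification for the synthetic 2AFC task
#'
#' Describes one simulated session of the orientation-discrimination task:
#' how stimuli are drawn and, optionally, the ground-truth decision model
#' that generates choices. Defaults reproduce the task conditions: the
#' correct-side orientation is drawn from the horizontal-heavy prior,
#' verticality differences span 20-90 degrees in 10 degree steps, a small
#' fraction of trials shows the same orientation on both sides, and the
#' two contrasts are drawn independently from `{0.3, 0.6, 1}`.
#'
#' @param n_trials Number of base trials.
#' @param env_id Reward environment id.
#' @param truth Ground-truth model: an [observer_params()] or
#'   [dm_params()] object (may be `NULL` for stimulus-only generation).
#' @param difficulties Verticality-difference set in degrees.
#' @param equal_fraction Fraction of equal-orientation trials.
#' @param contrasts Contrast set.
#' @param prior An [orientation_prior()] tibble.
#' @param repeat_incorrect If `TRUE`, each incorrect trial is followed by
#'   repeats with the same correct side (resampled orientations), marked
#'   `excluded = TRUE` as in the training protocol; fits ignore excluded
#'   rows.
#' @param seed Master seed for the session.
#' @return A list of class `ri_session_spec`.
#' @export
session_spec <- function(n_trials = 5000,
                         env_id = c("constant", "increasing", "decreasing"),
                         truth = NULL,
                         difficulties = task_difficulties(),
                         equal_fraction = 0.02,
                         contrasts = task_contrasts(),
                         prior = orientation_prior(),
                         repeat_incorrect = FALSE,
                         seed = 1) {
  env_id <- match.arg(env_id)
  stopifnot(n_trials >= 1, equal_fraction >= 0, equal_fraction <= 1)
  if (!is.null(truth) && !inherits(truth, c("ri_observer", "ri_dm"))) {
    stop("`truth` must be observer_params() or dm_params().", call. = FALSE)
  }
  structure(list(
    n_trials = n_trials, env_id = env_id, truth = truth,
    difficulties = difficulties, equal_fraction = equal_fraction,
    contrasts = contrasts, prior = prior,
    repeat_incorrect = repeat_incorrect, seed = seed
  ), class = "ri_session_spec")
}

.draw_stimuli <- function(spec, n, seed_offset = 0) {
  prior <- spec$prior
  withr::with_seed(spec$seed + seed_offset, {
    # the correct-side orientation must admit at least one difficulty;
    # draws that admit none are resampled (bounded retries)
    theta_c <- numeric(n)
    pending <- seq_len(n)
    tries <- 0
    while (length(pending)) {
      tries <- tries + 1
      if (tries > 200) {
        stop("could not place stimuli for the requested difficulty set.",
          call. = FALSE
        )
      }
      th <- sample_prior(prior, length(pending))
      ok <- verticality(th) >= min(spec$difficulties)
      theta_c[pending[ok]] <- th[ok]
      pending <- pending[!ok]
    }
    # difficulty drawn uniformly from the feasible subset per trial
    d <- vapply(theta_c, function(th) {
      feas <- spec$difficulties[spec$difficulties <= verticality(th)]
      feas[sample.int(length(feas), 1)]
    }, numeric(1))
    v_other <- verticality(theta_c) - d
    # two orientations share each verticality value; pick one at random
    flip <- stats::runif(n) < 0.5
    theta_o <- ifelse(flip & v_other > 0, (180 - v_other) %% 180, v_other)
    tie <- stats::runif(n) < spec$equal_fraction
    theta_o[tie] <- theta_c[tie]
    corr_left <- stats::runif(n) < 0.5
    tibble::tibble(
      trial = seq_len(n),
      theta_l = ifelse(corr_left, theta_c, theta_o),
      theta_r = ifelse(corr_left, theta_o, theta_c),
      c_l = sample(spec$contrasts, n, replace = TRUE),
      c_r = sample(spec$contrasts, n, replace = TRUE),
      env_id = spec$env_id,
      tie = tie,
      correct_side = ifelse(tie, NA_character_,
        ifelse(corr_left, "left", "right")
      )
    )
  })
}

#' Generate task stimuli
#'
#' Draws the stimulus side of a session (no choices): per trial the
#' correct-side orientation comes from the prior (resampled until it
#' admits a difficulty), the verticality difference is drawn uniformly
#' from the feasible subset of the difficulty set, sides are randomized,
#' and contrasts are drawn independently.
#'
#' @param spec An [session_spec()] object.
#' @return A stimulus-only trial tibble.
#' @export
generate_trials <- function(spec) {
  stopifnot(inherits(spec, "ri_session_spec"))
  .draw_stimuli(spec, spec$n_trials)
}

#' Simulate a full behavioral session
#'
#' Generates stimuli and closed-loop choices from the ground-truth model
#' in `spec$truth` (observer or descriptive model), applies the reward
#' environment (correct choices rewarded by the correct-side orientation;
#' equal-orientation trials rewarded on a random side), and fills the
#' history columns `prev_choice` and `prev_reward`. With
#' `repeat_incorrect = TRUE` incorrect trials are followed by excluded
#' repeat trials with the same correct side.
#'
#' @param spec An [session_spec()] object with non-`NULL` `truth`.
#' @return A trial tibble with columns `choice`, `correct`, `reward`,
#'   `prev_choice`, `prev_reward`, `excluded` in addition to the stimulus
#'   columns.
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "ri_session_spec"))
  if (is.null(spec$truth)) stop("`spec$truth` must be set.", call. = FALSE)
  base <- generate_trials(spec)
  env <- reward_environment(spec$env_id)
  truth <- spec$truth

  # stimulus-dependent part of the probit argument, no history terms
  z_base_of <- function(tab) {
    if (inherits(truth, "ri_observer")) {
      .choice_z(tab, truth, spec$prior, with_bias = FALSE) +
        truth$beta0 + truth$beta2 * (tab$c_l - tab$c_r)
    } else {
      dv <- verticality(tab$theta_l) - verticality(tab$theta_r)
      s <- if (truth$model == "DM1") {
        truth$sigma * sqrt(2)
      } else {
        sqrt(.dm_sigma_of(truth, tab$c_l)^2 + .dm_sigma_of(truth, tab$c_r)^2)
      }
      z <- dv / s + truth$beta0
      if (truth$model %in% c("DM3", "DM4", "DM5", "DM6")) {
        z <- z + truth$beta2 * (tab$c_l - tab$c_r)
      }
      z
    }
  }
  p_of <- function(z, D, prev_reward) {
    if (inherits(truth, "ri_observer")) {
      stats::pnorm(z + truth$beta1 * D)
    } else {
      zz <- z + truth$beta1 * D
      if (truth$model %in% c("DM5", "DM6")) {
        zz <- zz + truth$beta3 * D * prev_reward
      }
      phi <- stats::pnorm(zz)
      if (truth$model %in% c("DM4", "DM6")) {
        phi * (1 - truth$lapse_left - truth$lapse_right) + truth$lapse_left
      } else {
        phi * (1 - truth$lapse) + truth$lapse / 2
      }
    }
  }

  z_base <- z_base_of(base)
  max_repeats <- 5L

  # fast vectorized path when choices do not depend on trial history
  history_free <- if (inherits(truth, "ri_observer")) {
    truth$beta1 == 0
  } else {
    truth$beta1 == 0 &&
      (!(truth$model %in% c("DM5", "DM6")) || truth$beta3 == 0)
  }
  if (history_free && !spec$repeat_incorrect) {
    return(withr::with_seed(spec$seed + 1L, {
      p <- p_of(z_base, D = 0, prev_reward = 0)
      choice <- ifelse(stats::runif(spec$n_trials) < p, "left", "right")
      rewarded <- ifelse(base$tie,
        sample(c("left", "right"), spec$n_trials, replace = TRUE),
        base$correct_side
      )
      correct <- ifelse(base$tie, NA, choice == base$correct_side)
      theta_ch <- ifelse(choice == "left", base$theta_l, base$theta_r)
      reward <- ifelse(choice == rewarded, reward_for(env, theta_ch), 0)
      dplyr::mutate(base,
        choice = choice, correct = correct, reward = reward,
        prev_choice = dplyr::lag(choice, default = "none"),
        prev_reward = dplyr::lag(reward, default = 0),
        excluded = FALSE
      )
    }))
  }

  withr::with_seed(spec$seed + 1L, {
    rows <- vector("list", spec$n_trials * 2L)
    nrow_out <- 0L
    prev_choice <- "none"
    prev_reward <- 0
    rep_budget <- 0L
    repeat_row <- NULL
    i <- 1L
    while (i <= spec$n_trials || !is.null(repeat_row)) {
      if (!is.null(repeat_row)) {
        row <- repeat_row
        zb <- z_base_of(row)
        excl <- TRUE
      } else {
        row <- base[i, ]
        zb <- z_base[i]
        excl <- FALSE
        i <- i + 1L
      }
      D <- .prev_D(prev_choice)
      p <- p_of(zb, D, prev_reward)
      choice <- ifelse(stats::runif(1) < p, "left", "right")
      if (isTRUE(row$tie)) {
        rewarded <- sample(c("left", "right"), 1)
        correct <- NA
        got <- choice == rewarded
      } else {
        correct <- choice == row$correct_side
        got <- correct
      }
      theta_ch <- if (choice == "left") row$theta_l else row$theta_r
      reward <- if (got) reward_for(env, theta_ch) else 0
      out <- row
      out$choice <- choice
      out$correct <- correct
      out$reward <- reward
      out$prev_choice <- prev_choice
      out$prev_reward <- prev_reward
      out$excluded <- excl
      nrow_out <- nrow_out + 1L
      rows[[nrow_out]] <- out
      # queue a repeat after an incorrect, non-tie trial
      if (spec$repeat_incorrect && isFALSE(correct) && rep_budget < max_repeats) {
        rep_budget <- rep_budget + 1L
        rs <- spec
        rs$n_trials <- 1L
        rs$equal_fraction <- 0
        rr <- .draw_stimuli(rs, 1L, seed_offset = 7000L + nrow_out)
        # force the same correct side
        if (!identical(rr$correct_side, row$correct_side)) {
          rr <- dplyr::mutate(rr,
            theta_l = .data$theta_r, theta_r = .data$theta_l,
            c_l = .data$c_r, c_r = .data$c_l,
            correct_side = row$correct_side
          )
        }
        rr$trial <- row$trial
        repeat_row <- rr
      } else {
        if (isTRUE(correct) || isTRUE(row$tie) || !spec$repeat_incorrect ||
          rep_budget >= max_repeats) {
          repeat_row <- NULL
          rep_budget <- 0L
        }
      }
      prev_choice <- choice
      prev_reward <- reward
    }
    out <- dplyr::bind_rows(rows[seq_len(nrow_out)])
  })
  out$trial <- seq_len(nrow(out))
  out
}

.trial_schema <- c(
  trial = "integer", theta_l = "numeric", theta_r = "numeric",
  c_l = "numeric", c_r = "numeric", env_id = "character",
  tie = "logical", correct_side = "character", choice = "character",
  correct = "logical", reward = "numeric", prev_choice = "character",
  prev_reward = "numeric", excluded = "logical", covariate = "character"
)

#' Write a trial table to CSV
#'
#' @param trials Trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Restores column types from the trial-table schema and validates that
#' the stimulus columns are present.
#'
#' @param path CSV path written by [write_trials()].
#' @param required Columns that must be present.
#' @return A trial tibble.
#' @export
read_trials <- function(path, required = c("theta_l", "theta_r", "c_l", "c_r")) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  missing <- setdiff(required, names(header))
  if (length(missing)) {
    stop(sprintf(
      "trial table %s is missing column(s): %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  classes <- .trial_schema[names(header)]
  classes[is.na(classes)] <- "NA"
  names(classes) <- names(header)
  out <- tryCatch(
    utils::read.csv(path,
      check.names = FALSE, na.strings = "",
      colClasses = unname(classes)
    ),
    error = function(e) {
      stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  tibble::as_tibble(out)
}
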