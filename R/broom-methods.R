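#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model fit
#'
#' One row per estimated parameter, on the natural scale where a
#' transform was used during optimization (`log_*` and `lg_*` prefixes
#' are back-transformed).
#'
#' @param x An `ri_fit` object.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` columns.
#' @export
tidy.ri_fit <- function(x, ...) {
  if (is.data.frame(x$estimates)) {
    return(tidyr::pivot_longer(x$estimates, -"level",
      names_to = "term", values_to = "estimate"
    ))
  }
  nm <- names(x$estimates)
  est <- unname(x$estimates)
  natural <- ifelse(startsWith(nm, "log_"), exp(est),
    ifelse(startsWith(nm, "lg_lapse"), 0.5 * stats::plogis(est),
      ifelse(nm == "lg_lapse", stats::plogis(est),
        ifelse(startsWith(nm, "lg_"), stats::plogis(est), est)
      )
    )
  )
  term <- sub("^log_", "", sub("^lg_", "", nm))
  tibble::tibble(term = term, estimate = natural)
}

#' Glance at a model fit
#'
#' @param x An `ri_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the fit summary (log-likelihood,
#'   AIC/BIC, sizes).
#' @export
glance.ri_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_id, logLik = x$logLik, AIC = x$AIC, BIC = x$BIC,
    n_trials = x$n_trials, n_params = x$n_params,
    converged = any(x$diagnostics$convergence == 0)
  )
}

#' Tidy an optimization result
#'
#' @param x An `ri_opt` object from [optimize_gain()].
#' @param ... Unused.
#' @return The optimal gain as a tibble (`theta`, `g`) with the
#'   coefficient and `k_max` columns repeated per row dropped in favour
#'   of attributes.
#' @export
tidy.ri_opt <- function(x, ...) {
  tibble::tibble(theta = x$gain$theta, g = x$gain$g)
}

#' Glance at an optimization result
#'
#' @param x An `ri_opt` object.
#' @param ... Unused.
#' @return One-row tibble with the objective decomposition.
#' @export
glance.ri_opt <- function(x, ...) {
  tibble::tibble(
    env = x$env_id, k_max = x$k_max, objective = x$objective,
    loss = x$loss, cost = x$cost, expected_reward = x$expected_reward
  )
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf(
    "<ri_fit> %s: logLik %.2f, AIC %.1f, BIC %.1f (%d params, %d trials)\n",
    x$model_id, x$logLik, x$AIC, x$BIC, x$n_params, x$n_trials
  ))
  invisible(x)
}

#' @export
print.ri_opt <- function(x, ...) {
  cat(sprintf(
    "<ri_opt> %s: objective %.4f = loss %.4f + cost %.4f; k_max %.2f\n",
    x$env_id, x$objective, x$loss, x$cost, x$k_max
  ))
  invisible(x)
}
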