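#' Polynomial resource gain family
#'
#' Builds a resource gain function g(theta) from polynomial coefficients.
#' On the normalized half-domain x in `[0, 1]` (horizontal to vertical) the
#' cumulative allocation is
#' `G(x) = x * (1 + (x - 1) * (g0 + g1*x + g2*x^2 + ...))`,
#' which satisfies G(0) = 0 and G(1) = 1 for any coefficients; its
#' derivative g = G' is sampled on the half grid, mirrored onto the second
#' half of orientation space (the prior is symmetric about vertical), and
#' normalized to mean 1 so that the gain integrates to 1 over the
#' normalized domain. `coef = c(0, 0, 0)` gives the uniform allocation.
#'
#' Coefficients for which G is not strictly increasing (g would go
#' non-positive somewhere) are invalid; the optimizer treats them as a
#' rejection penalty.
#'
#' @param coef Numeric coefficient vector `(g0, ..., gp)`; default order
#'   p = 2, i.e. three coefficients.
#' @param step Orientation grid step in degrees.
#' @return A tibble of class `ri_gain` with columns `theta`, `g`, and
#'   attributes `coef` and `step`.
#' @examples
#' resource_gain(c(0, 0, 0))    # uniform
#' resource_gain(c(0.5, 0, 0))  # tilted toward vertical
#' @export
resource_gain <- function(coef = c(0, 0, 0), step = 2) {
  if (!gain_coef_valid(coef)) {
    stop("invalid gain coefficients: G(x) is not strictly increasing on [0, 1].",
      call. = FALSE
    )
  }
  theta <- orientation_grid(step)
  half <- theta[theta < 90]
  x <- half / 90
  gh <- .gain_deriv(x, coef)
  g <- c(gh, rev(gh))
  g <- g / mean(g)
  out <- tibble::tibble(theta = theta, g = g)
  attr(out, "coef") <- coef
  attr(out, "step") <- step
  class(out) <- c("ri_gain", class(out))
  out
}

# G(x) and its analytic derivative on the normalized half-domain
.gain_cum <- function(x, coef) {
  p <- outer(x, seq_along(coef) - 1, `^`) %*% coef
  x * (1 + (x - 1) * drop(p))
}

.gain_deriv <- function(x, coef) {
  pows <- seq_along(coef) - 1
  p <- drop(outer(x, pows, `^`) %*% coef)
  dp <- if (length(coef) > 1) {
    drop(outer(x, pmax(pows - 1, 0), `^`) %*% (coef * pows))
  } else {
    rep(0, length(x))
  }
  1 + (2 * x - 1) * p + (x^2 - x) * dp
}

#' Validity of gain coefficients
#'
#' Checks that the cumulative allocation G is strictly increasing on
#' `[0, 1]` (equivalently g > 0 everywhere), on a fine check grid.
#'
#' @param coef Coefficient vector.
#' @param n_check Number of check points.
#' @return Logical scalar.
#' @export
gain_coef_valid <- function(coef, n_check = 201) {
  if (!is.numeric(coef) || any(!is.finite(coef))) {
    return(FALSE)
  }
  x <- seq(0, 1, length.out = n_check)
  all(.gain_deriv(x, coef) > 1e-10)
}

#' Gain object from raw grid values
#'
#' Wraps an arbitrary positive vector of per-orientation gains (e.g. the
#' divisively normalized reward belief of the learning model) as an
#' `ri_gain`, renormalized to mean 1.
#'
#' @param g Positive numeric vector, one value per grid orientation.
#' @param step Grid step in degrees.
#' @param floor Small value zero entries are lifted to (relative to the
#'   maximum); the learning model's floored belief can contain exact
#'   zeros, but an encoding gain must stay positive. The default 0
#'   rejects non-positive values instead.
#' @return An `ri_gain` tibble (attribute `coef` is `NULL`).
#' @export
gain_from_values <- function(g, step = 2, floor = 0) {
  theta <- orientation_grid(step)
  if (length(g) != length(theta)) {
    stop("`g` must have one value per grid orientation.", call. = FALSE)
  }
  if (any(!is.finite(g))) {
    stop("gain values must be finite.", call. = FALSE)
  }
  if (floor > 0) g <- pmax(g, floor * max(g))
  if (any(g <= 0)) {
    stop("gain values must be finite and positive.", call. = FALSE)
  }
  g <- g / mean(g)
  out <- tibble::tibble(theta = theta, g = g)
  attr(out, "coef") <- NULL
  attr(out, "step") <- step
  class(out) <- c("ri_gain", class(out))
  out
}
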