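#' Psychometric curve
#'
#' Fraction of rightward choices as a function of the signed verticality
#' difference `verticality(theta_r) - verticality(theta_l)`, with
#' binomial standard errors. Differences are binned on a regular grid;
#' bins with no trials are reported as `NA`, not zero.
#'
#' @param trials Trial table with a `choice` column.
#' @param bin_width Bin width in degrees (default 10, the task's
#'   difficulty step).
#' @return A tibble of class `ri_psych` with columns `diff` (bin
#'   center), `n`, `p_right`, `se`.
#' @export
psychometric_curve <- function(trials, bin_width = 10) {
  if (!nrow(trials)) stop("empty trial table.", call. = FALSE)
  dv <- verticality(trials$theta_r) - verticality(trials$theta_l)
  ctr <- round(dv / bin_width) * bin_width
  grid <- seq(min(ctr), max(ctr), by = bin_width)
  agg <- tibble::tibble(diff = ctr, right = trials$choice == "right") |>
    dplyr::group_by(.data$diff) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$right), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(diff = grid), agg, by = "diff") |>
    dplyr::mutate(
      p_right = .data$k / .data$n,
      se = sqrt(.data$p_right * (1 - .data$p_right) / .data$n)
    ) |>
    dplyr::select("diff", "n", "p_right", "se")
  class(out) <- c("ri_psych", class(out))
  out
}

#' Pairwise discriminability (dissimilarity) matrix
#'
#' Psychometric distances between orientations on a coarse angle grid:
#' each entry is the probability of a correct discrimination of the pair
#' minus 0.5, so the diagonal is exactly zero and entries lie in
#' `[0, 0.5]`. From a fitted/constructed observer the entries come from
#' the model's bias-free error probability averaged over the contrast
#' pair product; from a trial table they are pooled empirical accuracies
#' per unordered orientation pair.
#'
#' @param x An [observer_params()] object or a trial table with `choice`
#'   and `correct_side` columns.
#' @param ... Further arguments passed to methods.
#' @return A symmetric matrix of class `ri_dissim` with the angle grid in
#'   `dimnames` and attribute `grid`.
#' @export
build_dissimilarity <- function(x, ...) UseMethod("build_dissimilarity")

#' @rdname build_dissimilarity
#' @param prior An [orientation_prior()] tibble.
#' @param grid Angle grid in degrees (default 0-170 in 10 degree steps).
#' @param contrasts Contrast set pooled over.
#' @export
build_dissimilarity.ri_observer <- function(x, prior,
                                            grid = seq(0, 170, by = 10),
                                            contrasts = task_contrasts(), ...) {
  n <- length(grid)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  cp <- expand.grid(c_l = contrasts, c_r = contrasts)
  perr <- matrix(0, n, n)
  for (k in seq_len(nrow(cp))) {
    tr <- tibble::tibble(
      theta_l = grid[pairs$i], theta_r = grid[pairs$j],
      c_l = cp$c_l[k], c_r = cp$c_r[k]
    )
    perr <- perr + matrix(error_probability(tr, x, prior)$p_error, n, n)
  }
  d <- 0.5 - perr / nrow(cp)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(grid, grid)
  attr(d, "grid") <- grid
  class(d) <- c("ri_dissim", class(d))
  d
}

#' @rdname build_dissimilarity
#' @export
build_dissimilarity.data.frame <- function(x, grid = seq(0, 170, by = 10), ...) {
  need <- c("theta_l", "theta_r", "choice", "correct_side")
  if (!all(need %in% names(x))) {
    stop("trial table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  x <- x[!is.na(x$correct_side), ]
  snap <- function(th) grid[pmin(
    pmax(round(th / diff(grid)[1]) + 1, 1),
    length(grid)
  )]
  a <- snap(x$theta_l)
  b <- snap(x$theta_r)
  n <- length(grid)
  num <- den <- matrix(0, n, n)
  ia <- match(a, grid)
  ib <- match(b, grid)
  corr <- x$choice == x$correct_side
  for (t in seq_along(ia)) {
    i <- ia[t]
    j <- ib[t]
    den[i, j] <- den[i, j] + 1
    num[i, j] <- num[i, j] + corr[t]
    den[j, i] <- den[j, i] + 1
    num[j, i] <- num[j, i] + corr[t]
  }
  v <- verticality(grid)
  tie_pair <- abs(outer(v, v, `-`)) < 1e-9 # no defined correct side: distance 0
  if (any(den == 0 & !tie_pair)) {
    stop("unsampled orientation pair(s); pool more trials or use a model.",
      call. = FALSE
    )
  }
  d <- num / pmax(den, 1) - 0.5
  d[tie_pair] <- 0
  diag(d) <- 0
  d <- pmin(pmax(d, 0), 0.5)
  dimnames(d) <- list(grid, grid)
  attr(d, "grid") <- grid
  class(d) <- c("ri_dissim", class(d))
  d
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Metric MDS by double-centered eigendecomposition (via
#' [stats::cmdscale()]), with a deterministic sign convention per axis so
#' embeddings are reproducible. Also reports the normalized stress of
#' the embedding.
#'
#' @param d An `ri_dissim` matrix (or any symmetric dissimilarity
#'   matrix).
#' @param dims Number of embedding dimensions.
#' @return A tibble of class `ri_mds` with columns `theta` and `dim1`,
#'   `dim2`, ..., and attributes `eig` and `stress`.
#' @export
mds_embedding <- function(d, dims = 2) {
  m <- unclass(d)
  attr(m, "grid") <- NULL
  if (!isSymmetric(m, tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric.", call. = FALSE)
  }
  fit <- stats::cmdscale(m, k = dims, eig = TRUE)
  pts <- fit$points
  for (k in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, k])), k] < 0) pts[, k] <- -pts[, k]
  }
  emb_d <- as.matrix(stats::dist(pts))
  stress <- sqrt(sum((m - emb_d)^2) / sum(m^2))
  grid <- attr(d, "grid")
  if (is.null(grid)) grid <- as.numeric(rownames(m))
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(pts), paste0("dim", seq_len(ncol(pts)))
  ))
  out <- dplyr::bind_cols(tibble::tibble(theta = grid), out)
  attr(out, "eig") <- fit$eig
  attr(out, "stress") <- stress
  class(out) <- c("ri_mds", class(out))
  out
}

#' Mean pairwise embedding distance within an orientation band
#'
#' Average distance between embedded nodes whose verticality falls in
#' `band` (degrees). Used to compare the geometric expansion of
#' near-vertical versus near-horizontal orientations across reward
#' environments.
#'
#' @param emb An `ri_mds` embedding.
#' @param band Verticality range `c(lo, hi)`.
#' @return Mean pairwise distance (scalar).
#' @export
band_distance <- function(emb, band) {
  v <- verticality(emb$theta)
  sel <- v >= band[1] & v <= band[2]
  if (sum(sel) < 2) stop("fewer than two nodes in the band.", call. = FALSE)
  pts <- as.matrix(emb[sel, grep("^dim", names(emb)), drop = FALSE])
  mean(stats::dist(pts))
}
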