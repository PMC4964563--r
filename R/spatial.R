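# Quadrat-count analysis of colony point patterns: density, chi-square
# style statistic, and Monte Carlo test against complete spatial
# randomness (CSR).

#' Construct a point pattern in a rectangular window
#'
#' @param points Data frame with numeric columns `x` and `y` (metres).
#' @param window Numeric vector `c(x_min, x_max, y_min, y_max)` in metres.
#' @return A `foundress_ppp` object.
#' @examples
#' point_pattern(data.frame(x = runif(10, 0, 100), y = runif(10, 0, 100)),
#'               window = c(0, 100, 0, 100))
#' @export
point_pattern <- function(points, window) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)),
            length(window) == 4L, is.numeric(window))
  window <- as.numeric(window)
  if (window[2L] <= window[1L] || window[4L] <= window[3L]) {
    stop("window must have positive area", call. = FALSE)
  }
  if (nrow(points) > 0L &&
      (any(points$x < window[1L]) || any(points$x > window[2L]) ||
       any(points$y < window[3L]) || any(points$y > window[4L]))) {
    stop("all points must lie inside the window", call. = FALSE)
  }
  structure(
    list(points = tibble::tibble(x = as.numeric(points$x),
                                 y = as.numeric(points$y)),
         window = window),
    class = "foundress_ppp"
  )
}

#' @export
print.foundress_ppp <- function(x, ...) {
  w <- x$window
  cat(sprintf("<foundress_ppp> %d points in [%g, %g] x [%g, %g] m\n",
              nrow(x$points), w[1L], w[2L], w[3L], w[4L]))
  invisible(x)
}

#' @describeIn point_pattern Scatter plot of the pattern.
#' @param object A `foundress_ppp` object.
#' @param ... Unused.
#' @export
autoplot.foundress_ppp <- function(object, ...) {
  w <- object$window
  ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::coord_fixed(xlim = w[1:2], ylim = w[3:4], expand = FALSE) +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = "Colony locations")
}

#' Point density in colonies per hectare
#'
#' Total point count divided by window area, converted from square metres
#' to hectares (1 ha = 10,000 m^2).
#'
#' @param pattern A [point_pattern()].
#' @return Density in points per hectare.
#' @export
pattern_density <- function(pattern) {
  stopifnot(inherits(pattern, "foundress_ppp"))
  w <- pattern$window
  area_m2 <- (w[2L] - w[1L]) * (w[4L] - w[3L])
  nrow(pattern$points) / (area_m2 / 1e4)
}

# quadrat index (1..n_x*n_y) of every point; half-open cells, with points
# on the upper window boundary assigned to the last row/column
quadrat_of <- function(x, y, window, n_x, n_y) {
  ix <- pmin(floor((x - window[1L]) / (window[2L] - window[1L]) * n_x), n_x - 1L)
  iy <- pmin(floor((y - window[3L]) / (window[4L] - window[3L]) * n_y), n_y - 1L)
  as.integer(iy * n_x + ix + 1L)
}

#' Chi-square-type quadrat statistic
#'
#' Splits the window into `n_x` x `n_y` equal-area rectangular quadrats and
#' returns `sum((O - E)^2 / E)` over quadrats, with `E = n / (n_x n_y)`
#' everywhere, the classic test statistic for departure from a uniform
#' intensity. Quadrats are half-open so every point falls in exactly one.
#'
#' @param pattern A [point_pattern()] with at least one point.
#' @param n_x,n_y Number of quadrat columns / rows; `n_x * n_y >= 2`.
#' @return The statistic (numeric scalar).
#' @export
quadrat_statistic <- function(pattern, n_x, n_y) {
  stopifnot(inherits(pattern, "foundress_ppp"))
  n_x <- check_count(n_x, "n_x", min = 1L)
  n_y <- check_count(n_y, "n_y", min = 1L)
  if (n_x * n_y < 2L) stop("need at least two quadrats", call. = FALSE)
  n <- nrow(pattern$points)
  if (n == 0L) stop("pattern has no points", call. = FALSE)
  counts <- tabulate(quadrat_of(pattern$points$x, pattern$points$y,
                                pattern$window, n_x, n_y),
                     nbins = n_x * n_y)
  e <- n / (n_x * n_y)
  sum((counts - e)^2 / e)
}

#' Monte Carlo quadrat test of complete spatial randomness
#'
#' Compares the observed [quadrat_statistic()] with its distribution under
#' CSR, estimated from `n_sim` simulated patterns of the same point count
#' placed uniformly in the same window. The p-value uses the plus-one
#' estimator `p = (1 + #{simulated >= observed}) / (n_sim + 1)`, which is
#' valid by construction; its smallest attainable value is
#' `1 / (n_sim + 1)`. A Monte Carlo reference is used instead of the
#' chi-square distribution because quadrat expectations are often small.
#' The default is the upper tail (clustering inflates the statistic); set
#' `alternative = "two.sided"` to also flag excessive regularity.
#'
#' @inheritParams quadrat_statistic
#' @param n_sim Number of CSR simulations (default 1999).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `quadrat_test` object: list with `statistic`, `p_value`,
#'   `n_x`, `n_y`, `n_sim`, `alternative`, `n_points` and the vector of
#'   `sim_statistics`.
#' @export
quadrat_mc_test <- function(pattern, n_x, n_y, n_sim = 1999L, seed = NULL,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n_sim <- check_count(n_sim, "n_sim", min = 1L)
  obs <- quadrat_statistic(pattern, n_x, n_y)
  n <- nrow(pattern$points)
  w <- pattern$window
  k <- n_x * n_y
  e <- n / k
  sims <- with_seed_maybe(seed, {
    # all simulated quadrat indices at once: n_sim x n uniform points
    qx <- quadrat_of(runif(n_sim * n, w[1L], w[2L]),
                     runif(n_sim * n, w[3L], w[4L]), w, n_x, n_y)
    sim_id <- rep(seq_len(n_sim), each = n)
    counts <- tabulate(qx + (sim_id - 1L) * k, nbins = n_sim * k)
    rowSums(matrix((counts - e)^2 / e, nrow = n_sim, ncol = k, byrow = TRUE))
  })
  p_upper <- (1 + sum(sims >= obs - 1e-12)) / (n_sim + 1)
  p <- if (alternative == "greater") {
    p_upper
  } else {
    p_lower <- (1 + sum(sims <= obs + 1e-12)) / (n_sim + 1)
    min(1, 2 * min(p_upper, p_lower))
  }
  structure(
    list(statistic = obs, p_value = p, n_x = n_x, n_y = n_y,
         n_sim = n_sim, alternative = alternative, n_points = n,
         sim_statistics = sims),
    class = "quadrat_test"
  )
}

#' @export
print.quadrat_test <- function(x, ...) {
  cat(sprintf("Monte Carlo quadrat test of CSR (%d x %d quadrats, %d points)\n",
              x$n_x, x$n_y, x$n_points))
  cat(sprintf("  statistic = %.3f, p = %.4g (%d simulations, %s)\n",
              x$statistic, x$p_value, x$n_sim, x$alternative))
  invisible(x)
}

#' @describeIn quadrat_mc_test One-row tibble of the test result.
#' @param x A `quadrat_test` object.
#' @param ... Unused.
#' @export
glance.quadrat_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_x = x$n_x, n_y = x$n_y, n_sim = x$n_sim,
                 n_points = x$n_points, alternative = x$alternative)
}

#' @describeIn quadrat_mc_test Null distribution with the observed
#'   statistic marked.
#' @param object A `quadrat_test` object.
#' @export
autoplot.quadrat_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(statistic = object$sim_statistics),
                  ggplot2::aes(.data$statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::labs(x = "Quadrat statistic under CSR", y = "Simulations",
                  title = sprintf("Observed statistic %.1f, Monte Carlo p = %.4g",
                                  object$statistic, object$p_value))
}

#' Repeat the quadrat test over a range of quadrat sizes
#'
#' Runs [quadrat_mc_test()] once per grid in `grids`, to guard against an
#' arbitrary choice of quadrat size. No multiplicity adjustment is applied;
#' the `consistent_departure` attribute flags whether every size rejected
#' at `alpha`.
#'
#' @inheritParams quadrat_mc_test
#' @param grids List of `c(n_x, n_y)` pairs.
#' @param alpha Significance level for the consistency flag.
#' @return A tibble with one row per grid (`n_x`, `n_y`, `statistic`,
#'   `p_value`, `n_sim`), with attribute `consistent_departure`.
#' @export
quadrat_size_scan <- function(pattern, grids, n_sim = 1999L, seed = NULL,
                              alpha = 0.05,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(grids) >= 1L)
  seeds <- with_seed_maybe(seed, child_seeds(length(grids)))
  rows <- purrr::map2(grids, seeds, function(g, s) {
    glance(quadrat_mc_test(pattern, g[1L], g[2L], n_sim = n_sim, seed = s,
                           alternative = alternative))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "consistent_departure") <- all(out$p_value <= alpha)
  out
}
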