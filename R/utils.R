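# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed when one is given; otherwise use
# (and advance) the caller's RNG stream. All stochastic user-facing functions
# route their randomness through this so a `seed` argument never leaks state.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

# Draw k child seeds from the current stream; used to give each phase /
# generation / replicate its own reproducible stream.
child_seeds <- function(k) {
  sample.int(.Machine$integer.max - 1L, k)
}

#' Toroidal distance between lattice cells
#'
#' Euclidean distance between cell centres on a square lattice with
#' wraparound (torus) boundaries, the metric used throughout the
#' colony-founding simulation. Inputs are recycled.
#'
#' @param row1,col1,row2,col2 Integer cell coordinates (1-based).
#' @param n_side Lattice side length in cells.
#' @return Numeric vector of distances, each at most `n_side * sqrt(2) / 2`.
#' @examples
#' torus_distance(1, 1, 1, 10, n_side = 10)  # wraps: distance 1
#' @export
torus_distance <- function(row1, col1, row2, col2, n_side) {
  stopifnot(n_side >= 1)
  dr <- abs(row1 - row2) %% n_side
  dc <- abs(col1 - col2) %% n_side
  dr <- pmin(dr, n_side - dr)
  dc <- pmin(dc, n_side - dc)
  sqrt(dr^2 + dc^2)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1]", call. = FALSE)
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}
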