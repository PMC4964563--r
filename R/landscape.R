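#' Generate a toroidal landscape of nest sites
#'
#' Each cell of an `n_side` x `n_side` torus is independently suitable for
#' colony foundation with probability `p_suitable`. Distances between cells
#' wrap around both edges ([torus_distance()]), so the landscape has no
#' boundary effects.
#'
#' @param n_side Side length in cells (>= 1).
#' @param p_suitable Per-cell suitability probability.
#' @param seed Optional integer seed for reproducibility.
#' @return A `foundress_landscape`: list with `n_side` and a logical
#'   `suitable` matrix.
#' @examples
#' land <- generate_landscape(10, 0.5, seed = 1)
#' mean(land$suitable)
#' @export
generate_landscape <- function(n_side, p_suitable, seed = NULL) {
  n_side <- check_count(n_side, "n_side", min = 1L)
  check_prob(p_suitable, "p_suitable")
  suitable <- with_seed_maybe(seed, {
    matrix(runif(n_side^2) < p_suitable, n_side, n_side)
  })
  structure(list(n_side = n_side, suitable = suitable),
            class = "foundress_landscape")
}

#' @export
print.foundress_landscape <- function(x, ...) {
  cat(sprintf("<foundress_landscape> %d x %d torus, %d / %d cells suitable\n",
              x$n_side, x$n_side, sum(x$suitable), x$n_side^2))
  invisible(x)
}

#' @describeIn generate_landscape Tidy the landscape into one row per cell
#'   (`row`, `col`, `suitable`).
#' @param x A `foundress_landscape`.
#' @param ... Unused.
#' @export
tidy.foundress_landscape <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(x$n_side), times = x$n_side),
    col = rep(seq_len(x$n_side), each = x$n_side),
    suitable = as.vector(x$suitable)
  )
}

# 0-based cell index (row-major, matching the C++ kernels) from 1-based
# (row, col) and back.
cell_index0 <- function(row, col, n_side) {
  (row - 1L) * n_side + (col - 1L)
}
cell_row <- function(cell0, n_side) cell0 %/% n_side + 1L
cell_col <- function(cell0, n_side) cell0 %% n_side + 1L

# Unique wrap offsets (dr, dc in 0..n_side-1) reaching every cell within
# toroidal distance <= r of a focal cell, each exactly once. Includes (0, 0).
disk_offsets <- function(n_side, r) {
  d <- 0:(n_side - 1L)
  ax <- pmin(d, n_side - d)                 # per-axis toroidal displacement
  keep <- outer(ax^2, ax^2, "+") <= r^2 + 1e-9
  idx <- which(keep, arr.ind = TRUE)
  list(dr = d[idx[, 1L]], dc = d[idx[, 2L]])
}
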