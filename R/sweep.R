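# Parameter sweeps over interaction radii and foundress density, and the
# interaction-radius threshold above which the tolerant phenotype fixes.

#' Specify a radius x density parameter sweep
#'
#' Defines the grid of clustering radii, territory radii and cohort sizes
#' (densities) over which [run_sweep()] replicates the simulation. With
#' `tie_radii = TRUE` (the default, matching the usual presentation of the
#' model's results) a single `r` vector is used for both radii and the grid
#' runs along the diagonal `r_cluster == r_territory`.
#'
#' @param r Radii used for both `r_cluster` and `r_territory` when
#'   `tie_radii` is `TRUE`.
#' @param r_cluster,r_territory Radius grids when `tie_radii` is `FALSE`.
#' @param m Cohort sizes (the model's "population sizes"); with
#'   `base_params$n_side` fixed these set the foundress density.
#' @param replicates Runs per grid point.
#' @param base_params A [model_params()] object supplying all other
#'   parameters.
#' @param seed Root seed; every `(grid point, replicate)` run receives its
#'   own child seed drawn once from this root, so replicates are
#'   exchangeable and the whole table reproduces bit for bit.
#' @param tie_radii Run along the `r_cluster == r_territory` diagonal?
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(r = c(0, 1, 2, 4, 8, 16),
                       r_cluster = r, r_territory = r,
                       m = c(125L, 250L, 500L),
                       replicates = 20L,
                       base_params = model_params(n_side = 50L,
                                                  n_generations = 50L),
                       seed = 1L,
                       tie_radii = TRUE) {
  replicates <- check_count(replicates, "replicates", min = 1L)
  stopifnot(length(r_cluster) >= 1L, length(r_territory) >= 1L,
            length(m) >= 1L, all(r_cluster >= 0), all(r_territory >= 0),
            inherits(base_params, "foundress_params"))
  grid <- if (tie_radii) {
    tidyr::expand_grid(r_cluster = sort(unique(r_cluster)),
                       m = sort(unique(as.integer(m)))) |>
      dplyr::mutate(r_territory = .data$r_cluster, .after = "r_cluster")
  } else {
    tidyr::expand_grid(r_cluster = sort(unique(r_cluster)),
                       r_territory = sort(unique(r_territory)),
                       m = sort(unique(as.integer(m))))
  }
  structure(list(grid = grid, replicates = replicates,
                 base_params = base_params, seed = seed,
                 tie_radii = tie_radii),
            class = "sweep_spec")
}

#' Run a replicated parameter sweep
#'
#' Runs [run_simulation()] `replicates` times at every grid point of a
#' [sweep_spec()], each run under its own deterministic child seed.
#'
#' @param spec A [sweep_spec()].
#' @return A `foundress_sweep` tibble with one row per run: the grid
#'   coordinates, `replicate`, `seed`, `final_share`, `fixed_phenotype`
#'   and `extinct`. The spec is attached as attribute `spec`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  runs <- tidyr::expand_grid(spec$grid,
                             replicate = seq_len(spec$replicates))
  runs$seed <- with_seed_maybe(spec$seed, child_seeds(nrow(runs)))
  res <- purrr::pmap(runs, function(r_cluster, r_territory, m, replicate, seed) {
    p <- spec$base_params
    p$r_cluster <- r_cluster
    p$r_territory <- r_territory
    p$m <- as.integer(m)
    sim <- run_simulation(p, seed = seed)
    tibble::tibble(final_share = sim$history$coop_share[nrow(sim$history)],
                   fixed_phenotype = sim$fixed_phenotype,
                   extinct = sim$extinct)
  })
  out <- dplyr::bind_cols(runs, dplyr::bind_rows(res))
  attr(out, "spec") <- spec
  class(out) <- c("foundress_sweep", class(out))
  out
}

#' Summarise a sweep into fixation fractions per grid point
#'
#' @param result A [run_sweep()] table.
#' @return A tibble with one row per grid point: `n` runs, `coop_fixed`
#'   count, `coop_fixation_fraction` and its binomial standard error.
#' @export
summarize_sweep <- function(result) {
  result |>
    dplyr::group_by(.data$r_cluster, .data$r_territory, .data$m) |>
    dplyr::summarise(
      n = dplyr::n(),
      coop_fixed = sum(.data$fixed_phenotype == "cooperative", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coop_fixation_fraction = .data$coop_fixed / .data$n,
      se = sqrt(.data$coop_fixation_fraction *
                  (1 - .data$coop_fixation_fraction) / .data$n)
    )
}

#' Estimate the interaction-radius threshold for tolerant fixation
#'
#' The threshold is the smallest radius at which the cooperative-fixation
#' fraction reaches 0.5, with linear interpolation between the two grid
#' radii that straddle 0.5. By default the scan runs along the
#' `r_cluster == r_territory` diagonal (`tie_radii` sweeps). If the
#' fraction is at or above 0.5 already at the smallest radius, that radius
#' is returned; if it never reaches 0.5, the threshold is `NA` ("no
#' threshold in range").
#'
#' @param result A [run_sweep()] table (or [summarize_sweep()] output).
#' @param m Cohort size selecting the density slice.
#' @return A one-row tibble: `m`, `threshold`, `n_radii`.
#' @export
estimate_threshold <- function(result, m) {
  summ <- if ("coop_fixation_fraction" %in% names(result)) result
          else summarize_sweep(result)
  summ <- summ |>
    dplyr::filter(.data$m == !!m, .data$r_cluster == .data$r_territory) |>
    dplyr::arrange(.data$r_cluster)
  if (nrow(summ) == 0L) stop("no diagonal grid points at m = ", m, call. = FALSE)
  r <- summ$r_cluster
  f <- summ$coop_fixation_fraction
  thr <- if (f[1L] >= 0.5) {
    r[1L]
  } else if (all(f < 0.5)) {
    NA_real_
  } else {
    j <- which(f >= 0.5)[1L]
    r[j - 1L] + (0.5 - f[j - 1L]) * (r[j] - r[j - 1L]) / (f[j] - f[j - 1L])
  }
  tibble::tibble(m = m, threshold = thr, n_radii = length(r))
}

#' @describeIn run_sweep Heat map of the cooperative-fixation fraction over
#'   radius and density.
#' @param object A `foundress_sweep` table.
#' @param ... Unused.
#' @export
autoplot.foundress_sweep <- function(object, ...) {
  summ <- summarize_sweep(object)
  ggplot2::ggplot(summ,
                  ggplot2::aes(factor(.data$r_cluster), factor(.data$m),
                               fill = .data$coop_fixation_fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "P(tolerant fixes)") +
    ggplot2::labs(x = "Interaction radius (cells)",
                  y = "Foundresses per generation (m)",
                  title = "Fixation of the tolerant phenotype by radius and density")
}
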