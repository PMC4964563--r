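#' Simulation parameters for the colony-founding model
#'
#' Bundles and validates every parameter of the two-phase (foundation /
#' growth) agent-based model of cooperative colony founding. Defaults follow
#' the published description of the model where values are stated (fight
#' mortalities 0.40/0.60, 200 generations, initial cooperative share 0.05,
#' productivity peak at six queens) and otherwise use documented design
#' choices.
#'
#' @param n_side Side of the square toroidal landscape, in cells.
#' @param p_suitable Probability that a cell is a suitable nest site.
#' @param m Number of new foundress queens per generation. The foundress
#'   density is `m / n_side^2` queens per cell.
#' @param x_c0 Initial share of the cooperative (tolerant) phenotype.
#' @param p_initiate Probability that an aggressive queen initiates a fight
#'   when a pair of co-founding queens is evaluated.
#' @param p_death_aggressor Probability that the aggressor dies in a fight
#'   against a cooperative queen (0.40). Exactly one queen dies per fight,
#'   so the cooperator dies otherwise.
#' @param p_death_cooperator Probability that the cooperative queen dies in
#'   such a fight (0.60). Must equal `1 - p_death_aggressor`.
#' @param p_mutate Probability that an offspring queen switches phenotype.
#' @param r_cluster Clustering radius: queens move to the cell within this
#'   toroidal distance holding the most other queens.
#' @param r_territory Territory radius of a growing colony; two colonies
#'   compete when their territories overlap (see `overlap_rule`).
#' @param n_generations Number of generations to simulate.
#' @param productivity_peak Queen number at which colony productivity peaks.
#' @param fixation_threshold Share at (or above) which a phenotype is scored
#'   as fixed at the end of a run; mutation keeps literal fixation out of
#'   reach, so this operationalises "went to fixation".
#' @param overlap_rule `"disk-disk"` (territories of radius `r_territory`
#'   overlap when centres are within `2 * r_territory`) or
#'   `"center-in-disk"` (within `r_territory`).
#' @param productivity_fun Optional replacement productivity function taking
#'   `(x, peak)`; `NULL` uses the built-in unimodal form, see
#'   [productivity()].
#'
#' @details
#' `p_initiate` and `p_mutate` have no published point value. Their
#' defaults (0.25 and 0.005) are chosen so that the model operates in the
#' empirically motivated regime where an initially rare tolerant phenotype
#' can invade once interaction radii are large: with certain initiation
#' (`p_initiate = 1`) every mixed foundress group collapses to a single
#' surviving queen and a rare tolerant phenotype cannot invade at any
#' radius or density. The methods vignette derives this in detail.
#'
#' @return A validated `foundress_params` list.
#' @seealso [run_simulation()], [read_model_config()]
#' @examples
#' model_params(n_side = 50, m = 250, r_cluster = 4, r_territory = 4)
#' @export
model_params <- function(n_side = 100L,
                         p_suitable = 0.5,
                         m = 1000L,
                         x_c0 = 0.05,
                         p_initiate = 0.25,
                         p_death_aggressor = 0.40,
                         p_death_cooperator = 0.60,
                         p_mutate = 0.005,
                         r_cluster = 2,
                         r_territory = 2,
                         n_generations = 200L,
                         productivity_peak = 6L,
                         fixation_threshold = 0.95,
                         overlap_rule = c("disk-disk", "center-in-disk"),
                         productivity_fun = NULL) {
  overlap_rule <- match.arg(overlap_rule)
  p <- list(
    n_side = check_count(n_side, "n_side", min = 1L),
    p_suitable = check_prob(p_suitable, "p_suitable"),
    m = check_count(m, "m", min = 0L),
    x_c0 = check_prob(x_c0, "x_c0"),
    p_initiate = check_prob(p_initiate, "p_initiate"),
    p_death_aggressor = check_prob(p_death_aggressor, "p_death_aggressor"),
    p_death_cooperator = check_prob(p_death_cooperator, "p_death_cooperator"),
    p_mutate = check_prob(p_mutate, "p_mutate"),
    r_cluster = r_cluster,
    r_territory = r_territory,
    n_generations = check_count(n_generations, "n_generations", min = 1L),
    productivity_peak = check_count(productivity_peak, "productivity_peak", min = 1L),
    fixation_threshold = check_prob(fixation_threshold, "fixation_threshold"),
    overlap_rule = overlap_rule,
    productivity_fun = productivity_fun
  )
  if (!is.numeric(r_cluster) || r_cluster < 0 ||
      !is.numeric(r_territory) || r_territory < 0) {
    stop("radii must be non-negative", call. = FALSE)
  }
  if (abs(p$p_death_aggressor + p$p_death_cooperator - 1) > 1e-8) {
    stop("`p_death_cooperator` must equal 1 - `p_death_aggressor`: ",
         "every fight between an aggressor and a cooperator kills exactly ",
         "one of the two", call. = FALSE)
  }
  if (!is.null(productivity_fun) && !is.function(productivity_fun)) {
    stop("`productivity_fun` must be NULL or a function(x, peak)", call. = FALSE)
  }
  structure(p, class = "foundress_params")
}

#' @export
print.foundress_params <- function(x, ...) {
  cat("<foundress_params>\n")
  cat(sprintf("  landscape   : %d x %d torus, p_suitable = %g\n",
              x$n_side, x$n_side, x$p_suitable))
  cat(sprintf("  queens      : m = %d per generation (density %.4f / cell), x_c0 = %g\n",
              x$m, x$m / x$n_side^2, x$x_c0))
  cat(sprintf("  fights      : p_initiate = %g, aggressor dies %.2f / cooperator %.2f\n",
              x$p_initiate, x$p_death_aggressor, x$p_death_cooperator))
  cat(sprintf("  radii       : r_cluster = %g, r_territory = %g (%s)\n",
              x$r_cluster, x$r_territory, x$overlap_rule))
  cat(sprintf("  dynamics    : %d generations, p_mutate = %g, productivity peak %d, fixation >= %g\n",
              x$n_generations, x$p_mutate, x$productivity_peak,
              x$fixation_threshold))
  invisible(x)
}

#' Read model parameters from a YAML or JSON configuration file
#'
#' The file holds a flat mapping whose keys mirror the [model_params()]
#' argument names exactly; missing keys fall back to the defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML parses) file.
#' @return A `foundress_params` object.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of parameter names", call. = FALSE)
  unknown <- setdiff(names(cfg), names(formals(model_params)))
  if (length(unknown)) {
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_params, cfg)
}
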