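#' Published summary tables of the foundress experiments
#'
#' Returns, as plain R objects, the printed tables and counts that the
#' package's statistics are checked against: the frequency-of-aggression
#' table by source population and treatment, the 2x2 tables behind the
#' population comparison and the field foundress-group-size comparison,
#' the death counts, and a deterministic per-queen record set
#' (`table1_records`) whose marginal counts reproduce the aggression table
#' exactly. The record set is synthetic — the raw laboratory data were not
#' released — and its death days are an arbitrary deterministic spread;
#' only its counts are meaningful.
#'
#' A fresh copy is built on every call, so the fixtures behave as
#' immutable constants.
#'
#' @return A list:
#' \describe{
#'   \item{aggression_by_population}{Tibble of the printed table: stratum,
#'     aggressive and total queen counts, displayed proportion.}
#'   \item{population_table}{2x2 matrix (population x aggressive/tolerant,
#'     all-groups rows): chi-square 14.8.}
#'   \item{group_size_table}{2x2 matrix (site x multi-/single-queen
#'     nests): chi-square 23.9.}
#'   \item{deaths}{List: `n_deaths = 229`, `n_aggression_deaths = 46`.}
#'   \item{table1_records}{Per-queen record tibble reproducing the counts
#'     above, including 229 deaths of which 46 by aggression.}
#' }
#' @examples
#' fx <- foundress_fixtures()
#' pearson_chisq(fx$group_size_table)
#' @export
foundress_fixtures <- function() {
  aggression_by_population <- tibble::tibble(
    stratum = c("P (6P)", "P (1H:5P)", "P (1H:1P)",
                "H (1H:5P)", "H (1H:1P)",
                "P (all groups)", "H (all groups)"),
    n_aggressive = c(23L, 6L, 3L, 6L, 7L, 32L, 13L),
    n_total = c(180L, 95L, 19L, 19L, 20L, 294L, 39L),
    proportion = c(0.13, 0.06, 0.15, 0.32, 0.35, 0.11, 0.33)
  )
  population_table <- matrix(
    c(32L, 13L, 262L, 26L), nrow = 2L,
    dimnames = list(population = c("pleometrotic", "haplometrotic"),
                    phenotype = c("aggressive", "tolerant"))
  )
  group_size_table <- matrix(
    c(35L, 1L, 12L, 16L), nrow = 2L,
    dimnames = list(site = c("Pine Valley", "Lake Henshaw"),
                    nest = c("multi-queen", "single-queen"))
  )
  list(
    aggression_by_population = aggression_by_population,
    population_table = population_table,
    group_size_table = group_size_table,
    deaths = list(n_deaths = 229L, n_aggression_deaths = 46L),
    table1_records = table1_records()
  )
}

# Deterministic per-queen records matching the printed counts. Group
# treatments carry the printed phenotype counts; the 229 deaths (46 by
# aggression) are spread deterministically over queens and days.
table1_records <- function() {
  strata <- list(
    # treatment, population, n, n_aggressive, queens per group
    list("pure_group",  "pleometrotic",  180L, 23L, 6L),
    list("mixed_group", "pleometrotic",  95L,  6L,  5L),
    list("mixed_group", "haplometrotic", 19L,  6L,  1L),
    # the printed pair rows tabulate 19 pleometrotic but 20 haplometrotic
    # queens (one pleometrotic pair member is absent from the table)
    list("mixed_pair",  "pleometrotic",  19L,  3L,  1L),
    list("mixed_pair",  "haplometrotic", 20L,  7L,  1L),
    list("single_p",    "pleometrotic",  29L,  3L,  1L),
    list("single_h",    "haplometrotic", 21L,  7L,  1L)
  )
  rows <- purrr::map(strata, function(s) {
    n <- s[[3L]]
    per_group <- s[[5L]]
    tibble::tibble(
      treatment = s[[1L]],
      population = s[[2L]],
      phenotype = rep(c("aggressive", "tolerant"), c(s[[4L]], n - s[[4L]])),
      group_id = paste(s[[1L]], s[[2L]],
                       (seq_len(n) - 1L) %/% per_group + 1L, sep = "_")
    )
  })
  rec <- dplyr::bind_rows(rows)
  rec$queen_id <- seq_len(nrow(rec))
  # 229 deaths of which 46 by aggression, days cycling over the horizon
  n <- nrow(rec)                      # 383 queens
  cause <- rep("censored", n)
  cause[seq_len(46L)] <- "aggression"
  cause[47L:229L] <- "other"
  death_day <- rep(NA_integer_, n)
  death_day[seq_len(229L)] <- ((seq_len(229L) - 1L) %% 60L) + 1L
  rec$death_day <- death_day
  rec$cause <- cause
  dplyr::select(rec, "queen_id", "group_id", "treatment", "population",
                "phenotype", "death_day", "cause")
}
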