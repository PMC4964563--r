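# Contingency-table and aggression summaries for foundress experiments.

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic `sum((O - E)^2 / E)` with expectations from
#' the row/column margins, `(r - 1)(c - 1)` degrees of freedom and an
#' upper-tail chi-square p-value. No continuity correction is applied, for
#' any table size — note that many libraries silently Yates-correct 2x2
#' tables, which would not reproduce the uncorrected statistic reported
#' here.
#'
#' @param table Matrix (or data frame) of non-negative counts, at least
#'   2x2, with a positive grand total and no zero row/column margin.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' pearson_chisq(matrix(c(35, 1, 12, 16), nrow = 2))
#' @export
pearson_chisq <- function(table) {
  x <- as.matrix(table)
  mode(x) <- "numeric"
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(is.na(x)) || any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  if (n <= 0) stop("grand total must be positive", call. = FALSE)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column margin: expected counts undefined", call. = FALSE)
  }
  e <- outer(rs, cs) / n
  stat <- sum((x - e)^2 / e)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE))
}

# canonical stratum labels used in aggression summaries
treatment_labels <- c(
  single_h = "1H", single_p = "1P",
  mixed_pair = "1H:1P", pure_group = "6P", mixed_group = "1H:5P"
)
group_treatments <- c("mixed_pair", "pure_group", "mixed_group")

check_records <- function(records) {
  needed <- c("queen_id", "group_id", "treatment", "population",
              "phenotype", "death_day", "cause")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(records$population %in% c("haplometrotic", "pleometrotic")),
            all(records$phenotype %in% c("aggressive", "tolerant")),
            all(records$cause %in% c("aggression", "other", "censored")),
            all(is.na(records$death_day) | (records$death_day >= 1 &
                                              records$death_day <= 60)),
            all(records$cause == "censored" | !is.na(records$death_day)))
  invisible(records)
}

#' Tabulate the frequency of the aggressive phenotype by population
#'
#' Summarises foundress records into the standard "frequency of aggression"
#' layout: one row per source population x treatment stratum (e.g. the
#' pleometrotic queens of pure groups of six), plus an all-groups row per
#' population that aggregates the *group* treatments only (pairs and
#' groups; solitary queens are excluded because aggression toward
#' co-foundresses is undefined for them).
#'
#' @param records Foundress record tibble (see
#'   [simulate_foundress_experiment()] for the column contract).
#' @return A tibble: `stratum`, `population`, `treatment`, `n_aggressive`,
#'   `n_total`, `proportion` (exact) and `proportion_displayed` (rounded to
#'   2 decimals, the conventional display precision).
#' @export
aggression_table <- function(records) {
  if (nrow(records) == 0L) stop("records are empty", call. = FALSE)
  check_records(records)
  grp <- records |>
    dplyr::filter(.data$treatment %in% group_treatments)
  per <- grp |>
    dplyr::group_by(.data$population, .data$treatment) |>
    dplyr::summarise(
      n_aggressive = sum(.data$phenotype == "aggressive"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(stratum = paste0(
      toupper(substr(.data$population, 1L, 1L)),
      " (", treatment_labels[.data$treatment], ")"
    ))
  all_grp <- grp |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_aggressive = sum(.data$phenotype == "aggressive"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(treatment = "all_groups",
                  stratum = paste0(toupper(substr(.data$population, 1L, 1L)),
                                   " (all groups)"))
  dplyr::bind_rows(per, all_grp) |>
    dplyr::mutate(
      proportion = .data$n_aggressive / .data$n_total,
      proportion_displayed = round(.data$proportion, 2L)
    ) |>
    dplyr::select("stratum", "population", "treatment",
                  "n_aggressive", "n_total", "proportion",
                  "proportion_displayed")
}

#' Share of queen deaths attributable to aggression
#'
#' In the laboratory experiments a death is attributed to aggression when
#' the queen is found with head or abdomen severed; here the `cause` column
#' plays that role. Censored queens (alive at the horizon) are not deaths.
#'
#' @param records Foundress record tibble.
#' @return A one-row tibble: `n_deaths`, `n_aggression_deaths`, `fraction`
#'   and `percent` (rounded to the nearest integer percent, the display
#'   convention).
#' @export
aggression_death_fraction <- function(records) {
  check_records(records)
  deaths <- sum(records$cause != "censored")
  if (deaths == 0L) {
    stop("no deaths in the records: the fraction is undefined", call. = FALSE)
  }
  agg <- sum(records$cause == "aggression")
  tibble::tibble(
    n_deaths = deaths,
    n_aggression_deaths = agg,
    fraction = agg / deaths,
    percent = round(100 * agg / deaths)
  )
}
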