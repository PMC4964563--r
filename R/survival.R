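# Product-limit survival curves and the log-rank test, for inspecting
# synthetic foundress experiments. (Mixed-effects proportional-hazards
# modelling is deliberately not provided.)

km_times <- function(time, event) {
  ut <- sort(unique(time[event]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event)
}

#' Kaplan-Meier survival curves for foundress records
#'
#' Product-limit estimate of queen survival over the observation horizon,
#' by stratum. Queens with `cause == "censored"` are censored at the
#' horizon; all others die at `death_day`.
#'
#' @param records Foundress record tibble.
#' @param by Column name to stratify on (default `"treatment"`).
#' @param horizon Observation horizon in days (default 60).
#' @return A `foundress_km` tibble: `stratum`, `time`, `n_risk`,
#'   `n_event`, `survival` — an anchor row at time 0 (survival 1) plus one
#'   row per stratum x event time.
#' @export
kaplan_meier <- function(records, by = "treatment", horizon = 60) {
  check_records(records)
  if (!by %in% names(records)) stop("no column `", by, "` in records", call. = FALSE)
  strata <- split(records, records[[by]], drop = TRUE)
  if (any(vapply(strata, nrow, integer(1)) == 0L)) {
    stop("empty stratum", call. = FALSE)
  }
  out <- purrr::imap(strata, function(d, nm) {
    time <- ifelse(d$cause == "censored", horizon, d$death_day)
    event <- d$cause != "censored"
    tab <- km_times(time, event)
    tab$survival <- cumprod(1 - tab$n_event / tab$n_risk)
    # anchor the curve at time 0 with everyone at risk
    tab <- dplyr::bind_rows(
      tibble::tibble(time = 0, n_risk = nrow(d), n_event = 0, survival = 1),
      tab
    )
    tab$stratum <- nm
    tab
  })
  res <- dplyr::bind_rows(out) |>
    dplyr::select("stratum", "time", "n_risk", "n_event", "survival")
  class(res) <- c("foundress_km", class(res))
  attr(res, "horizon") <- horizon
  res
}

#' @describeIn kaplan_meier Step-function plot of the survival curves.
#' @param object A `foundress_km` tibble.
#' @param ... Unused.
#' @export
autoplot.foundress_km <- function(object, ...) {
  horizon <- attr(object, "horizon") %||% max(object$time)
  base <- object |>
    dplyr::group_by(.data$stratum) |>
    dplyr::reframe(time = c(0, .data$time, horizon),
                   survival = c(1, .data$survival,
                                .data$survival[length(.data$survival)]))
  ggplot2::ggplot(base, ggplot2::aes(.data$time, .data$survival,
                                     colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Day", y = "Survival", colour = NULL,
                  title = "Queen survival by stratum")
}

#' Two-sample log-rank test
#'
#' Standard log-rank comparison of the hazard in two strata; the statistic
#' is chi-square with 1 df under the null of equal hazards.
#'
#' @param records Foundress record tibble containing exactly two levels of
#'   `by` (or subset it first).
#' @param by Stratifying column (default `"treatment"`).
#' @param horizon Observation horizon in days.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, the observed
#'   and expected event counts per stratum.
#' @export
log_rank <- function(records, by = "treatment", horizon = 60) {
  check_records(records)
  g <- factor(records[[by]])
  if (nlevels(g) != 2L) stop("log_rank needs exactly two strata", call. = FALSE)
  if (any(table(g) == 0L)) stop("empty stratum", call. = FALSE)
  time <- ifelse(records$cause == "censored", horizon, records$death_day)
  event <- records$cause != "censored"
  ut <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1L])
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g == levels(g)[1L])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  tibble::tibble(
    statistic = stat, df = 1L,
    p_value = pchisq(stat, 1L, lower.tail = FALSE),
    observed_1 = o1, expected_1 = e1,
    observed_2 = sum(event) - o1, expected_2 = sum(event) - e1,
    stratum_1 = levels(g)[1L], stratum_2 = levels(g)[2L]
  )
}
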