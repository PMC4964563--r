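# Generators for synthetic foundress experiments and spatial point
# patterns. The foundress generator mirrors the laboratory design (five
# treatments, 60-day horizon) and is calibrated to the published anchors:
# aggressive-phenotype proportions near 0.33 (haplometrotic source) and
# 0.11 (pleometrotic source), and roughly 20% of deaths attributable to
# aggression.

#' The five-treatment foundress experiment design
#'
#' Default replicate counts follow the laboratory experiment: 21 solitary
#' haplometrotic queens, 29 solitary pleometrotic queens, 20 mixed pairs,
#' 30 pure groups of six pleometrotic queens, and 19 mixed groups of five
#' pleometrotic plus one haplometrotic queen, observed for 60 days.
#'
#' @param single_h,single_p,mixed_pair,pure_group,mixed_group Replicate
#'   counts per treatment.
#' @param horizon Observation horizon in days.
#' @return A tibble: `treatment`, `n_groups`, `n_pleo`, `n_haplo`, with
#'   attribute `horizon`.
#' @export
experiment_design <- function(single_h = 21L, single_p = 29L,
                              mixed_pair = 20L, pure_group = 30L,
                              mixed_group = 19L, horizon = 60L) {
  out <- tibble::tibble(
    treatment = c("single_h", "single_p", "mixed_pair", "pure_group",
                  "mixed_group"),
    n_groups = as.integer(c(single_h, single_p, mixed_pair, pure_group,
                            mixed_group)),
    n_pleo = c(0L, 1L, 1L, 6L, 5L),
    n_haplo = c(1L, 0L, 1L, 0L, 1L)
  )
  stopifnot(all(out$n_groups >= 0L))
  attr(out, "horizon") <- check_count(horizon, "horizon", min = 1L)
  out
}

#' Parameters of the synthetic foundress-experiment generator
#'
#' @param p_aggressive_h,p_aggressive_p Probability that a queen from the
#'   haplometrotic / pleometrotic source population carries the aggressive
#'   phenotype (defaults 0.33 and 0.11, the published population
#'   proportions).
#' @param baseline_hazard Daily probability of death from causes other
#'   than aggression.
#' @param attack_rate Daily probability that a living aggressive queen
#'   attacks a living tolerant nestmate.
#' @param p_death_aggressor Probability that the attacker, not her victim,
#'   dies in such a fight (the foundation-phase analogue, 0.40).
#' @return A `synth_params` list.
#' @details `baseline_hazard` and `attack_rate` defaults were chosen once
#'   so that, under the default design, roughly 60% of queens die within
#'   the horizon and aggression accounts for about 20% of deaths.
#' @export
synth_params <- function(p_aggressive_h = 0.33, p_aggressive_p = 0.11,
                         baseline_hazard = 0.012, attack_rate = 0.045,
                         p_death_aggressor = 0.40) {
  structure(list(
    p_aggressive_h = check_prob(p_aggressive_h, "p_aggressive_h"),
    p_aggressive_p = check_prob(p_aggressive_p, "p_aggressive_p"),
    baseline_hazard = check_prob(baseline_hazard, "baseline_hazard"),
    attack_rate = check_prob(attack_rate, "attack_rate"),
    p_death_aggressor = check_prob(p_death_aggressor, "p_death_aggressor")
  ), class = "synth_params")
}

# daily simulation of one foundress group; returns death_day / cause vectors
simulate_group_days <- function(aggressive, params, horizon) {
  n <- length(aggressive)
  alive <- rep(TRUE, n)
  death_day <- rep(NA_integer_, n)
  cause <- rep("censored", n)
  for (day in seq_len(horizon)) {
    if (!any(alive)) break
    # aggression: each living aggressor may attack a living tolerant nestmate
    if (n > 1L) {
      for (i in which(alive & aggressive)) {
        victims <- which(alive & !aggressive)
        if (length(victims) == 0L) break
        if (runif(1L) < params$attack_rate) {
          v <- victims[sample.int(length(victims), 1L)]
          dead <- if (runif(1L) < params$p_death_aggressor) i else v
          alive[dead] <- FALSE
          death_day[dead] <- day
          cause[dead] <- "aggression"
        }
      }
    }
    # baseline mortality
    for (i in which(alive)) {
      if (runif(1L) < params$baseline_hazard) {
        alive[i] <- FALSE
        death_day[i] <- day
        cause[i] <- "other"
      }
    }
  }
  list(death_day = death_day, cause = cause)
}

#' Simulate a synthetic foundress experiment
#'
#' Generates daily survival and aggression records for every queen of an
#' [experiment_design()]. Each queen draws her phenotype from her source
#' population's aggressive-phenotype probability; the group then runs day
#' by day to the horizon, with aggressive queens attacking tolerant
#' nestmates (either party can die, the attacker with
#' `p_death_aggressor`) on top of a baseline daily hazard. Deaths from
#' attacks are recorded with cause `"aggression"`, others `"other"`;
#' queens alive at the horizon are `"censored"`.
#'
#' @param design An [experiment_design()].
#' @param params A [synth_params()].
#' @param seed Optional integer seed.
#' @return A tibble of foundress records: `queen_id`, `group_id`,
#'   `treatment`, `population`, `phenotype`, `death_day`, `cause`.
#' @examples
#' rec <- simulate_foundress_experiment(seed = 1)
#' aggression_table(rec)
#' @export
simulate_foundress_experiment <- function(design = experiment_design(),
                                          params = synth_params(),
                                          seed = NULL) {
  stopifnot(inherits(params, "synth_params"))
  horizon <- attr(design, "horizon") %||% 60L
  with_seed_maybe(seed, {
    rows <- list()
    qid <- 0L
    gid <- 0L
    for (tr in seq_len(nrow(design))) {
      for (g in seq_len(design$n_groups[tr])) {
        gid <- gid + 1L
        population <- c(rep("pleometrotic", design$n_pleo[tr]),
                        rep("haplometrotic", design$n_haplo[tr]))
        p_agg <- ifelse(population == "haplometrotic",
                        params$p_aggressive_h, params$p_aggressive_p)
        aggressive <- runif(length(population)) < p_agg
        fate <- simulate_group_days(aggressive, params, horizon)
        rows[[gid]] <- tibble::tibble(
          queen_id = qid + seq_along(population),
          group_id = gid,
          treatment = design$treatment[tr],
          population = population,
          phenotype = ifelse(aggressive, "aggressive", "tolerant"),
          death_day = fate$death_day,
          cause = fate$cause
        )
        qid <- qid + length(population)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a spatial point pattern
#'
#' `"csr"` draws exactly `n` points uniformly in the window (complete
#' spatial randomness, the quadrat test's null). `"clustered"` is a simple
#' parent-offspring (Thomas-like) process: `n_parents` parent locations
#' uniform in the window, each of the `n` points attached to a uniformly
#' chosen parent and displaced by an isotropic Gaussian with standard
#' deviation `dispersal_sd`; displacements falling outside the window are
#' redrawn, so the pattern has exactly `n` points inside. With
#' `dispersal_sd = 0` offspring coincide with their parents (maximal
#' clustering).
#'
#' @param kind `"csr"` or `"clustered"`.
#' @param n Number of points.
#' @param window `c(x_min, x_max, y_min, y_max)` in metres.
#' @param n_parents Number of cluster centres (clustered only).
#' @param dispersal_sd Gaussian dispersal around the centre, metres.
#' @param seed Optional integer seed.
#' @return A [point_pattern()].
#' @export
simulate_point_pattern <- function(kind = c("csr", "clustered"), n = 100L,
                                   window = c(0, 100, 0, 100),
                                   n_parents = 10L, dispersal_sd = 2,
                                   seed = NULL) {
  kind <- match.arg(kind)
  n <- check_count(n, "n", min = 0L)
  if (length(window) != 4L || window[2L] <= window[1L] ||
      window[4L] <= window[3L]) {
    stop("window must be c(x_min, x_max, y_min, y_max) with positive area",
         call. = FALSE)
  }
  with_seed_maybe(seed, {
    if (kind == "csr") {
      pts <- tibble::tibble(x = runif(n, window[1L], window[2L]),
                            y = runif(n, window[3L], window[4L]))
    } else {
      n_parents <- check_count(n_parents, "n_parents", min = 1L)
      if (dispersal_sd < 0) stop("dispersal_sd must be >= 0", call. = FALSE)
      px <- runif(n_parents, window[1L], window[2L])
      py <- runif(n_parents, window[3L], window[4L])
      parent <- sample.int(n_parents, n, replace = TRUE)
      x <- px[parent] + rnorm(n, 0, dispersal_sd)
      y <- py[parent] + rnorm(n, 0, dispersal_sd)
      bad <- which(x < window[1L] | x > window[2L] |
                     y < window[3L] | y > window[4L])
      while (length(bad) > 0L) {
        x[bad] <- px[parent[bad]] + rnorm(length(bad), 0, dispersal_sd)
        y[bad] <- py[parent[bad]] + rnorm(length(bad), 0, dispersal_sd)
        bad <- bad[x[bad] < window[1L] | x[bad] > window[2L] |
                     y[bad] < window[3L] | y[bad] > window[4L]]
      }
      pts <- tibble::tibble(x = x, y = y)
    }
    point_pattern(pts, window)
  })
}
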