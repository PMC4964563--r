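# One generation = foundation phase (placement, clustering, fights) then
# growth phase (territorial contests) then equal-share reproduction.

# Fast internal generation step on plain vectors. Returns NULL on extinction.
fd_generation <- function(landscape, coop, params, offsets, suitable0) {
  m <- length(coop)
  cell0 <- fd_place(landscape, m)
  if (params$r_cluster > 0) {
    cell0 <- fd_cluster(landscape, cell0, params$r_cluster, offsets, suitable0)
  }
  alive <- fd_fights(cell0, coop, params)
  fight_deaths <- sum(!alive)
  cols <- fd_colonies(cell0, coop, alive)
  n_colonies_pre <- length(cols$cell0)
  if (n_colonies_pre == 0L) return(NULL)
  elim <- fd_compete(cols, landscape$n_side, params)
  competition_deaths <- sum(cols$x[elim])
  surv <- list(cell0 = cols$cell0[!elim], x = cols$x[!elim],
               coop_k = cols$coop_k[!elim])
  rep_out <- fd_reproduce(surv, params)
  if (is.null(rep_out)) return(NULL)
  list(
    coop = rep_out$coop,
    parent_share = rep_out$share,
    n_colonies = length(surv$cell0),
    fight_deaths = fight_deaths,
    competition_deaths = competition_deaths
  )
}

#' Advance the colony-founding model by one generation
#'
#' Composes the model's phases: queens are placed on suitable cells,
#' cluster within `r_cluster`, fight within each occupied cell, the
#' survivors of each cell form one colony, overlapping colonies fight
#' elimination contests, and the survivors produce the next cohort with
#' equal colony shares.
#'
#' @param state A list with elements `landscape` (a
#'   [generate_landscape()] object) and `phenotypes` (character vector of
#'   `"cooperative"` / `"aggressive"` for the incoming cohort), as returned
#'   by this function or assembled by hand.
#' @param params A [model_params()] object; `params$m` must equal the
#'   cohort size.
#' @param seed Optional integer seed.
#' @return A list: `state` (next-generation `landscape` + `phenotypes`) and
#'   `stats`, a one-row tibble with `coop_share` (share in the new cohort),
#'   `parent_share` (landscape-level share the cohort was drawn from),
#'   `n_colonies`, `fight_deaths` and `competition_deaths`. `state` is
#'   `NULL` if the population went extinct.
#' @export
run_generation <- function(state, params, seed = NULL) {
  stopifnot(length(state$phenotypes) == params$m)
  with_seed_maybe(seed, {
    offsets <- disk_offsets(state$landscape$n_side, params$r_cluster)
    out <- fd_generation(state$landscape,
                         state$phenotypes == "cooperative",
                         params, offsets,
                         suitable_rowmajor(state$landscape))
    if (is.null(out)) {
      return(list(state = NULL, stats = tibble::tibble(
        coop_share = NA_real_, parent_share = NA_real_, n_colonies = 0L,
        fight_deaths = NA_integer_, competition_deaths = NA_integer_)))
    }
    list(
      state = list(
        landscape = state$landscape,
        phenotypes = ifelse(out$coop, "cooperative", "aggressive")
      ),
      stats = tibble::tibble(
        coop_share = mean(out$coop),
        parent_share = out$parent_share,
        n_colonies = out$n_colonies,
        fight_deaths = as.integer(out$fight_deaths),
        competition_deaths = as.integer(out$competition_deaths)
      )
    )
  })
}

#' Run the colony-founding simulation
#'
#' Simulates `n_generations` generations from an initial cohort with
#' cooperative share `x_c0`, recording the cooperative share of each
#' cohort. A phenotype is scored as fixed when its share at the final
#' recorded generation is at least `fixation_threshold` (cooperative) or at
#' most `1 - fixation_threshold` (aggressive). With `p_mutate = 0` the
#' shares 0 and 1 are absorbing and the run stops as soon as one is
#' reached.
#'
#' Randomness is controlled by a single root `seed`, from which the
#' landscape, the initial cohort and every generation receive child seeds
#' in a fixed documented order, so identical `(params, seed)` reproduce the
#' run bit for bit.
#'
#' @param params A [model_params()] object.
#' @param seed Integer root seed.
#' @return A `foundress_sim` object: list with `history` (tibble with one
#'   row per generation: `generation`, `coop_share`, `n_colonies`,
#'   `fight_deaths`, `competition_deaths`), `fixed_phenotype`
#'   (`"cooperative"`, `"aggressive"` or `NA`), `fixation_generation`,
#'   `extinct`, `seed` and `params`.
#' @examples
#' p <- model_params(n_side = 20, m = 40, n_generations = 10,
#'                   r_cluster = 2, r_territory = 2)
#' sim <- run_simulation(p, seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(params, seed = 1L) {
  stopifnot(inherits(params, "foundress_params"))
  seeds <- with_seed_maybe(seed, child_seeds(params$n_generations + 2L))
  landscape <- generate_landscape(params$n_side, params$p_suitable,
                                  seed = seeds[1L])
  coop <- with_seed_maybe(seeds[2L], runif(params$m) < params$x_c0)
  offsets <- disk_offsets(params$n_side, params$r_cluster)
  suitable0 <- suitable_rowmajor(landscape)

  g <- 0L
  share <- numeric(params$n_generations + 1L)
  n_col <- integer(params$n_generations + 1L)
  f_deaths <- integer(params$n_generations + 1L)
  c_deaths <- integer(params$n_generations + 1L)
  share[1L] <- if (params$m > 0) mean(coop) else NA_real_
  n_col[1L] <- NA_integer_; f_deaths[1L] <- NA_integer_; c_deaths[1L] <- NA_integer_
  extinct <- FALSE

  while (g < params$n_generations) {
    if (params$p_mutate == 0 && (share[g + 1L] == 0 || share[g + 1L] == 1)) {
      break  # absorbing state: the share can never change again
    }
    g <- g + 1L
    out <- with_seed_maybe(seeds[g + 2L], {
      fd_generation(landscape, coop, params, offsets, suitable0)
    })
    if (is.null(out)) {
      extinct <- TRUE
      g <- g - 1L
      break
    }
    coop <- out$coop
    share[g + 1L] <- mean(coop)
    n_col[g + 1L] <- out$n_colonies
    f_deaths[g + 1L] <- out$fight_deaths
    c_deaths[g + 1L] <- out$competition_deaths
  }

  idx <- seq_len(g + 1L)
  history <- tibble::tibble(
    generation = idx - 1L,
    coop_share = share[idx],
    n_colonies = n_col[idx],
    fight_deaths = f_deaths[idx],
    competition_deaths = c_deaths[idx]
  )

  final <- share[g + 1L]
  thr <- params$fixation_threshold
  fixed <- if (extinct || is.na(final)) NA_character_
           else if (final >= thr) "cooperative"
           else if (final <= 1 - thr) "aggressive"
           else NA_character_
  fix_gen <- NA_integer_
  if (!is.na(fixed)) {
    ok <- if (fixed == "cooperative") share[idx] >= thr else share[idx] <= 1 - thr
    # first generation from which the threshold held through to the end
    runs <- rev(cumprod(rev(ok)))
    fix_gen <- which(runs == 1)[1L] - 1L
  }

  structure(
    list(history = history, fixed_phenotype = fixed,
         fixation_generation = fix_gen, extinct = extinct,
         seed = seed, params = params),
    class = "foundress_sim"
  )
}

#' @export
print.foundress_sim <- function(x, ...) {
  h <- x$history
  cat(sprintf("<foundress_sim> %d generation(s), seed %s\n",
              max(h$generation), format(x$seed)))
  cat(sprintf("  cooperative share: %.3f -> %.3f\n",
              h$coop_share[1L], h$coop_share[nrow(h)]))
  if (x$extinct) {
    cat("  population went extinct\n")
  } else if (!is.na(x$fixed_phenotype)) {
    cat(sprintf("  %s phenotype fixed (threshold %.2f) from generation %d\n",
                x$fixed_phenotype, x$params$fixation_threshold,
                x$fixation_generation))
  } else {
    cat("  no phenotype fixed\n")
  }
  invisible(x)
}

#' @describeIn run_simulation Per-generation history as a tibble.
#' @param x A `foundress_sim` object.
#' @param ... Unused.
#' @export
tidy.foundress_sim <- function(x, ...) x$history

#' @describeIn run_simulation One-row summary: final share, fixation,
#'   extinction.
#' @export
glance.foundress_sim <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_generations = max(h$generation),
    final_share = h$coop_share[nrow(h)],
    fixed_phenotype = x$fixed_phenotype,
    fixation_generation = x$fixation_generation,
    extinct = x$extinct,
    seed = x$seed
  )
}

#' @describeIn run_simulation Trajectory of the cooperative share.
#' @param object A `foundress_sim` object.
#' @export
autoplot.foundress_sim <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$generation, .data$coop_share)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$fixation_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Cooperative share",
                  title = "Cooperative (tolerant) phenotype share over generations")
}
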