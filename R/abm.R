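# Foundation- and growth-phase operations of the colony-founding model.
#
# Internals (fd_*) work on plain vectors for speed and assume the caller has
# set the RNG state; the exported functions wrap them in tibbles and accept
# an optional `seed`.

fd_place <- function(landscape, m) {
  suitable_cells <- which(landscape$suitable) - 1L       # 0-based, column-major
  if (m > 0L && length(suitable_cells) == 0L) {
    stop("no suitable cells: queens cannot found colonies", call. = FALSE)
  }
  if (m == 0L) return(integer(0))
  # column-major matrix index -> (row, col) -> row-major 0-based index
  n <- landscape$n_side
  row <- suitable_cells %% n
  col <- suitable_cells %/% n
  cells0 <- row * n + col
  cells0[sample.int(length(cells0), m, replace = TRUE)]
}

fd_cluster <- function(landscape, cell0, r_cluster, offsets = NULL,
                       suitable0 = NULL) {
  m <- length(cell0)
  if (m == 0L) return(cell0)
  if (is.null(offsets)) offsets <- disk_offsets(landscape$n_side, r_cluster)
  if (is.null(suitable0)) suitable0 <- suitable_rowmajor(landscape)
  ord <- sample.int(m) - 1L
  cluster_pass_cpp(cell0, suitable0, landscape$n_side,
                   offsets$dr, offsets$dc, ord)
}

# suitability as a row-major logical vector (index (row-1)*n + (col-1)),
# the layout the C++ kernel expects
suitable_rowmajor <- function(landscape) {
  as.vector(t(landscape$suitable))
}

fd_fights <- function(cell0, coop, params) {
  alive <- rep(TRUE, length(cell0))
  if (length(cell0) < 2L) return(alive)
  groups <- split(seq_along(cell0), cell0)
  for (g in groups) {
    if (length(g) < 2L) next
    agg <- !coop[g]
    if (!any(agg)) next                       # all-cooperative cells are peaceful
    alive[g] <- fight_group_cpp(agg, params$p_initiate, params$p_death_aggressor)
  }
  alive
}

fd_colonies <- function(cell0, coop, alive) {
  keep <- which(alive)
  if (length(keep) == 0L) {
    return(list(cell0 = integer(0), x = integer(0), coop_k = integer(0)))
  }
  f <- factor(cell0[keep])
  x <- as.integer(tabulate(f))
  coop_k <- as.integer(rowsum(as.integer(coop[keep]), f))
  list(cell0 = as.integer(levels(f)), x = x, coop_k = coop_k)
}

fd_productivity <- function(x, params) {
  if (!is.null(params$productivity_fun)) {
    params$productivity_fun(x, params$productivity_peak)
  } else {
    x * exp(1 - x / params$productivity_peak)
  }
}

# Pairwise elimination contests between colonies with overlapping
# territories, nearest pairs first. Returns a logical eliminated flag.
fd_compete <- function(cols, n_side, params) {
  k <- length(cols$cell0)
  eliminated <- rep(FALSE, k)
  if (k < 2L || params$r_territory <= 0) return(eliminated)
  thr <- if (params$overlap_rule == "disk-disk") 2 * params$r_territory else params$r_territory
  row <- cell_row(cols$cell0, n_side)
  col <- cell_col(cols$cell0, n_side)
  pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  d <- torus_distance(row[pr[, 1L]], col[pr[, 1L]],
                      row[pr[, 2L]], col[pr[, 2L]], n_side)
  cand <- which(d <= thr + 1e-9)
  if (length(cand) == 0L) return(eliminated)
  ord <- cand[order(d[cand], runif(length(cand)))]   # ties in random order
  s <- fd_productivity(cols$x, params)
  for (p in ord) {
    i <- pr[p, 1L]; j <- pr[p, 2L]
    if (eliminated[i] || eliminated[j]) next
    tot <- s[i] + s[j]
    if (tot <= 0) stop("contest between two zero-productivity colonies", call. = FALSE)
    if (runif(1L) < s[i] / tot) eliminated[j] <- TRUE else eliminated[i] <- TRUE
  }
  eliminated
}

# Equal-share reproduction: landscape-level cooperative share is the
# unweighted mean of per-colony cooperative proportions; m offspring are
# drawn at that share, then mutate independently.
fd_reproduce <- function(cols, params) {
  k <- length(cols$cell0)
  if (k == 0L) return(NULL)                 # extinction, caller handles
  share <- mean(cols$coop_k / cols$x)
  coop <- runif(params$m) < share
  if (params$p_mutate > 0) {
    flip <- runif(params$m) < params$p_mutate
    coop <- xor(coop, flip)
  }
  list(share = share, coop = coop)
}

# ---- exported tibble API ---------------------------------------------------

queen_tibble <- function(cell0, coop, alive, n_side) {
  tibble::tibble(
    id = seq_along(cell0),
    phenotype = ifelse(coop, "cooperative", "aggressive"),
    row = cell_row(cell0, n_side),
    col = cell_col(cell0, n_side),
    alive = alive
  )
}

queen_cells0 <- function(queens, n_side) {
  cell_index0(queens$row, queens$col, n_side)
}

#' Place new foundress queens on the landscape
#'
#' Each of `m` queens lands on a uniformly chosen suitable cell;
#' phenotypes are drawn independently with probability `coop_share` of being
#' cooperative, unless an explicit `phenotypes` vector is supplied.
#'
#' @param landscape A [generate_landscape()] object.
#' @param m Number of queens.
#' @param coop_share Probability that a queen is cooperative.
#' @param seed Optional integer seed.
#' @param phenotypes Optional character vector (`"cooperative"` /
#'   `"aggressive"`) of length `m`, overriding `coop_share`.
#' @return A tibble of queens: `id`, `phenotype`, `row`, `col`, `alive`.
#' @export
seed_queens <- function(landscape, m, coop_share = 0.05, seed = NULL,
                        phenotypes = NULL) {
  m <- check_count(m, "m", min = 0L)
  check_prob(coop_share, "coop_share")
  if (!is.null(phenotypes)) {
    stopifnot(length(phenotypes) == m,
              all(phenotypes %in% c("cooperative", "aggressive")))
  }
  with_seed_maybe(seed, {
    cell0 <- fd_place(landscape, m)
    coop <- if (is.null(phenotypes)) runif(m) < coop_share
            else phenotypes == "cooperative"
    queen_tibble(cell0, coop, rep(TRUE, m), landscape$n_side)
  })
}

#' Cluster queens toward occupied nest sites
#'
#' In a uniformly random order, each queen moves to the suitable cell within
#' toroidal distance `r_cluster` of her current cell that holds the most
#' *other* queens at the moment of her move (her own cell is a candidate;
#' earlier moves are visible to later movers). Ties among positive counts
#' break uniformly at random; a queen with no other queen in reach stays
#' put. The rule is identical for both phenotypes.
#'
#' @param landscape A [generate_landscape()] object.
#' @param queens Queen tibble from [seed_queens()]; all must be alive.
#' @param r_cluster Clustering radius in cell units (0 disables movement).
#' @param seed Optional integer seed.
#' @return The queen tibble with updated `row` / `col`.
#' @export
cluster_queens <- function(landscape, queens, r_cluster, seed = NULL) {
  stopifnot(all(queens$alive), r_cluster >= 0)
  with_seed_maybe(seed, {
    cell0 <- fd_cluster(landscape, queen_cells0(queens, landscape$n_side),
                        r_cluster)
    queens$row <- cell_row(cell0, landscape$n_side)
    queens$col <- cell_col(cell0, landscape$n_side)
    queens
  })
}

#' Resolve fights among queens sharing a nest cell
#'
#' Every unordered pair of co-founding queens is evaluated once, in
#' uniformly random order; pairs with a dead member are skipped. A fight
#' happens when at least one aggressive member initiates (probability
#' `p_initiate` each); cooperative queens never initiate. Exactly one queen
#' dies per fight: between two aggressors each dies with probability 1/2;
#' between an aggressor and a cooperator the aggressor dies with
#' `p_death_aggressor` (default 0.40) and the cooperator otherwise (0.60).
#' At least one queen always survives.
#'
#' @param queens Queen tibble, all alive and on one cell (a foundress
#'   group).
#' @param params A [model_params()] object.
#' @param seed Optional integer seed.
#' @return The queen tibble with `alive` updated.
#' @export
resolve_fights <- function(queens, params, seed = NULL) {
  if (nrow(queens) == 0L) stop("empty foundress group", call. = FALSE)
  stopifnot(all(queens$alive),
            length(unique(paste(queens$row, queens$col))) == 1L)
  with_seed_maybe(seed, {
    agg <- queens$phenotype == "aggressive"
    queens$alive <- fight_group_cpp(agg, params$p_initiate,
                                    params$p_death_aggressor)
    queens
  })
}

#' Colony productivity as a function of queen number
#'
#' Competitive potential `s(x)` of a nascent colony with `x` queens: zero at
#' zero queens, rising to a peak at `productivity_peak` queens (six by
#' default, reflecting the head start that co-founding queens gain in
#' rearing a first workforce) and declining beyond it. The built-in form is
#' `s(x) = x * exp(1 - x / peak)`; a replacement can be plugged in through
#' `model_params(productivity_fun = )`.
#'
#' @param x Integer queen count(s), >= 0.
#' @param params A [model_params()] object.
#' @return Numeric vector of non-negative potentials.
#' @examples
#' p <- model_params()
#' productivity(0:10, p)
#' @export
productivity <- function(x, params = model_params()) {
  if (any(x < 0)) stop("queen count must be non-negative", call. = FALSE)
  fd_productivity(x, params)
}

#' Probability that one colony wins a pairwise contest
#'
#' A contest between colonies of sizes `x1` and `x2` is decided by relative
#' productivity: colony 1 wins with probability `s(x1) / (s(x1) + s(x2))`,
#' and the loser's queens all die.
#'
#' @param x1,x2 Queen counts of the two colonies (>= 1).
#' @param params A [model_params()] object.
#' @return Probability that colony 1 wins.
#' @export
contest_win_probability <- function(x1, x2, params = model_params()) {
  if (any(x1 < 1) || any(x2 < 1)) {
    stop("contests are defined for colonies with at least one queen", call. = FALSE)
  }
  s1 <- fd_productivity(x1, params)
  s2 <- fd_productivity(x2, params)
  if (any(s1 + s2 <= 0)) stop("contest undefined: both productivities zero", call. = FALSE)
  s1 / (s1 + s2)
}

#' Form nascent colonies from surviving queens
#'
#' Every cell still occupied after the foundation phase contributes exactly
#' one colony made of its surviving queens.
#'
#' @param queens Queen tibble (dead members allowed; they are dropped).
#' @return A colony tibble: `colony`, `row`, `col`, `x` (queen number),
#'   `coop_proportion`.
#' @export
form_colonies <- function(queens) {
  queens |>
    dplyr::filter(.data$alive) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      x = dplyr::n(),
      coop_proportion = mean(.data$phenotype == "cooperative"),
      .groups = "drop"
    ) |>
    dplyr::mutate(colony = dplyr::row_number(), .before = 1L)
}

#' Resolve territorial competition between colonies
#'
#' Colonies whose territories overlap fight pairwise elimination contests,
#' processed in increasing order of inter-colony distance (equal distances
#' in random order); pairs with an already-eliminated member are skipped.
#' In each contest one colony is eliminated — with the complement of its
#' [contest_win_probability()] — and all its queens die. Under the default
#' `"disk-disk"` rule two territories of radius `r_territory` overlap when
#' their centres are within `2 * r_territory`. On return no two surviving
#' colonies overlap.
#'
#' @param colonies Colony tibble from [form_colonies()].
#' @param landscape The landscape the colonies live on.
#' @param params A [model_params()] object.
#' @param seed Optional integer seed.
#' @return The colony tibble with a logical `eliminated` column.
#' @export
resolve_competition <- function(colonies, landscape, params, seed = NULL) {
  stopifnot(all(colonies$x >= 1))
  with_seed_maybe(seed, {
    cols <- list(
      cell0 = cell_index0(colonies$row, colonies$col, landscape$n_side),
      x = colonies$x,
      coop_k = round(colonies$coop_proportion * colonies$x)
    )
    if (anyDuplicated(cols$cell0)) {
      stop("colonies must occupy distinct cells", call. = FALSE)
    }
    colonies$eliminated <- fd_compete(cols, landscape$n_side, params)
    colonies
  })
}

#' Draw the next generation of foundress phenotypes
#'
#' Every surviving colony contributes an equal share of offspring,
#' regardless of its queen number: the landscape-level cooperative share is
#' the unweighted mean of per-colony cooperative proportions. `m` offspring
#' queens are drawn cooperative with that probability, then each switches
#' phenotype independently with `p_mutate`.
#'
#' @param colonies Surviving colony tibble (rows with `eliminated == TRUE`,
#'   if present, are dropped).
#' @param params A [model_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble of offspring (`id`, `phenotype`) with the parental
#'   landscape share attached as attribute `coop_share`.
#' @export
reproduce <- function(colonies, params, seed = NULL) {
  if ("eliminated" %in% names(colonies)) {
    colonies <- dplyr::filter(colonies, !.data$eliminated)
  }
  if (nrow(colonies) == 0L) {
    stop("no surviving colonies: the population is extinct", call. = FALSE)
  }
  with_seed_maybe(seed, {
    res <- fd_reproduce(
      list(cell0 = seq_len(nrow(colonies)),
           x = colonies$x,
           coop_k = colonies$coop_proportion * colonies$x),
      params
    )
    out <- tibble::tibble(
      id = seq_len(params$m),
      phenotype = ifelse(res$coop, "cooperative", "aggressive")
    )
    attr(out, "coop_share") <- res$share
    out
  })
}
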