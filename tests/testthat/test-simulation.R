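# Generation composition, conservation, absorbing states, determinism.

test_that("queens are conserved through a hand-composed generation", {
  for (s in 1:5) {
    land <- generate_landscape(20, 0.6, seed = s)
    p <- model_params(n_side = 20, m = 80, r_cluster = 3, r_territory = 2,
                      p_initiate = 1)
    q <- seed_queens(land, p$m, 0.3, seed = s + 10)
    q <- cluster_queens(land, q, p$r_cluster, seed = s + 20)
    fought <- q |>
      dplyr::group_split(row, col) |>
      purrr::imap(function(g, i) resolve_fights(g, p, seed = s * 100 + i)) |>
      dplyr::bind_rows()
    fight_deaths <- sum(!fought$alive)
    cols <- form_colonies(fought)
    expect_equal(sum(cols$x) + fight_deaths, p$m)
    out <- resolve_competition(cols, land, p, seed = s + 30)
    competition_deaths <- sum(out$x[out$eliminated])
    surv <- dplyr::filter(out, !eliminated)
    expect_equal(sum(surv$x) + fight_deaths + competition_deaths, p$m)
    # every occupied cell contributed exactly one colony
    occupied <- dplyr::n_distinct(paste(fought$row[fought$alive],
                                        fought$col[fought$alive]))
    expect_equal(nrow(cols), occupied)
  }
})

test_that("a generation without fights or contests is death-free", {
  p <- model_params(n_side = 15, m = 50, p_initiate = 0, r_territory = 0,
                    r_cluster = 2, n_generations = 5)
  land <- generate_landscape(15, 0.5, seed = 1)
  state <- list(landscape = land,
                phenotypes = rep(c("cooperative", "aggressive"), 25))
  out <- run_generation(state, p, seed = 2)
  expect_equal(out$stats$fight_deaths, 0L)
  expect_equal(out$stats$competition_deaths, 0L)
  expect_equal(length(out$state$phenotypes), 50L)
})

test_that("an all-aggressive cohort under certain initiation founds singleton colonies", {
  p <- model_params(n_side = 15, m = 60, p_initiate = 1, r_cluster = 3,
                    r_territory = 0)
  land <- generate_landscape(15, 0.8, seed = 5)
  q <- seed_queens(land, 60, 0, seed = 6, phenotypes = rep("aggressive", 60))
  q <- cluster_queens(land, q, 3, seed = 7)
  fought <- q |>
    dplyr::group_split(row, col) |>
    purrr::imap(function(g, i) resolve_fights(g, p, seed = i)) |>
    dplyr::bind_rows()
  cols <- form_colonies(fought)
  expect_true(all(cols$x == 1L))
})

test_that("monomorphic cohorts are absorbing without mutation", {
  p0 <- model_params(n_side = 15, m = 40, x_c0 = 0, p_mutate = 0,
                     n_generations = 15, r_cluster = 2, r_territory = 2)
  sim0 <- run_simulation(p0, seed = 3)
  expect_true(all(sim0$history$coop_share == 0))
  expect_identical(sim0$fixed_phenotype, "aggressive")

  p1 <- model_params(n_side = 15, m = 40, x_c0 = 1, p_mutate = 0,
                     n_generations = 15, r_cluster = 2, r_territory = 2)
  sim1 <- run_simulation(p1, seed = 3)
  expect_true(all(sim1$history$coop_share == 1))
  expect_identical(sim1$fixed_phenotype, "cooperative")
  # absorbing runs may stop early but never overrun
  expect_lte(nrow(sim1$history), p1$n_generations + 1)
})

test_that("identical seeds reproduce a simulation bit for bit", {
  p <- model_params(n_side = 25, m = 100, n_generations = 12,
                    r_cluster = 3, r_territory = 3)
  a <- run_simulation(p, seed = 11)
  b <- run_simulation(p, seed = 11)
  expect_identical(a, b)
  c <- run_simulation(p, seed = 12)
  expect_false(identical(a$history, c$history))
})

test_that("pair-fight outcomes match the closed-form enumeration oracle", {
  # exhaustive enumeration for a two-queen cell: an aggressive member
  # initiates with p_i; mixed fights kill the aggressor with p_df, two
  # aggressors flip a fair coin
  oracle_pair <- function(phenos, p_i, p_df) {
    agg <- phenos == "aggressive"
    if (sum(agg) == 0) return(c(none = 1, first = 0, second = 0))
    if (sum(agg) == 2) {
      p_fight <- 1 - (1 - p_i)^2
      c(none = 1 - p_fight, first = p_fight / 2, second = p_fight / 2)
    } else {
      p_fight <- p_i
      d_agg <- p_fight * p_df
      d_coop <- p_fight * (1 - p_df)
      if (agg[1]) c(none = 1 - p_fight, first = d_agg, second = d_coop)
      else        c(none = 1 - p_fight, first = d_coop, second = d_agg)
    }
  }
  p <- model_params(p_initiate = 0.7)
  cases <- list(c("aggressive", "cooperative"),
                c("cooperative", "aggressive"),
                c("aggressive", "aggressive"),
                c("cooperative", "cooperative"))
  n <- 20000
  for (phenos in cases) {
    g <- group_of(phenos)
    draws <- vapply(seq_len(n), function(s) {
      a <- resolve_fights(g, p, seed = s)$alive
      if (all(a)) "none" else if (!a[1]) "first" else "second"
    }, character(1))
    obs <- c(none = mean(draws == "none"), first = mean(draws == "first"),
             second = mean(draws == "second"))
    exp_p <- oracle_pair(phenos, 0.7, 0.4)
    for (k in names(exp_p)) {
      se <- sqrt(max(exp_p[k] * (1 - exp_p[k]), 1e-9) / n)
      expect_lt(abs(obs[k] - exp_p[k]), 3 * se + 1e-9)
    }
  }
})

test_that("tidy, glance and autoplot work on simulation results", {
  p <- model_params(n_side = 15, m = 30, n_generations = 8,
                    r_cluster = 2, r_territory = 2)
  sim <- run_simulation(p, seed = 2)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$generation[1], 0L)
  expect_true(all(td$coop_share >= 0 & td$coop_share <= 1))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$final_share, td$coop_share[nrow(td)])
  expect_s3_class(autoplot(sim), "ggplot")
})

test_that("config round-trip reproduces model parameters", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_side: 30", "m: 120", "r_cluster: 2.5", "r_territory: 2.5",
               "p_initiate: 0.4", "x_c0: 0.05"), cfg)
  p <- read_model_config(cfg)
  expect_s3_class(p, "foundress_params")
  expect_equal(p$n_side, 30L)
  expect_equal(p$r_cluster, 2.5)
  expect_equal(p$p_initiate, 0.4)
  writeLines("nonsense: 1", cfg)
  expect_error(read_model_config(cfg), "unknown parameter")
})
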