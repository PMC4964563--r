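# Growth phase: productivity, contests, territorial competition,
# reproduction.

test_that("productivity is zero at zero, peaks at six, declines beyond", {
  p <- model_params()
  expect_equal(productivity(0, p), 0)
  s <- productivity(1:20, p)
  expect_equal(which.max(s), 6L)
  expect_true(all(diff(s[1:6]) > 0))
  expect_true(all(diff(s[6:20]) < 0))
  expect_gt(s[6], s[1])
  expect_gt(s[6], s[12])
  expect_error(productivity(-1, p), "non-negative")
})

test_that("a plugged-in productivity function is honoured", {
  p <- model_params(productivity_fun = function(x, peak) ifelse(x > 0, 1, 0))
  expect_equal(productivity(c(0, 1, 10), p), c(0, 1, 1))
  expect_equal(contest_win_probability(2, 9, p), 0.5)
})

test_that("contest win probability follows relative productivity", {
  p <- model_params()
  expect_equal(contest_win_probability(4, 4, p), 0.5)
  # direct substitution of s(x) = x exp(1 - x/6)
  expected <- 6 * exp(0) / (6 * exp(0) + 1 * exp(1 - 1 / 6))
  expect_equal(contest_win_probability(6, 1, p), expected)
  expect_gt(expected, 0.5)
  for (x1 in c(1, 3, 6, 11)) for (x2 in c(1, 2, 8)) {
    expect_equal(contest_win_probability(x1, x2, p) +
                   contest_win_probability(x2, x1, p), 1)
  }
  expect_error(contest_win_probability(0, 3, p), "at least one")
})

test_that("lone and far-apart colonies are untouched by competition", {
  land <- flat_landscape(20)
  p <- tiny_params(r_territory = 2)
  one <- tibble::tibble(colony = 1L, row = 5L, col = 5L, x = 3L,
                        coop_proportion = 1)
  expect_false(resolve_competition(one, land, p, seed = 1)$eliminated)
  two <- tibble::tibble(colony = 1:2, row = c(1L, 10L), col = c(1L, 10L),
                        x = c(3L, 4L), coop_proportion = c(1, 0))
  expect_false(any(resolve_competition(two, land, p, seed = 1)$eliminated))
})

test_that("equal-size overlapping colonies are a fair contest, never both dying", {
  land <- flat_landscape(20)
  p <- tiny_params(r_territory = 2)
  two <- tibble::tibble(colony = 1:2, row = c(5L, 5L), col = c(5L, 8L),
                        x = c(3L, 3L), coop_proportion = c(1, 0))
  first_dies <- vapply(1:10000, function(s) {
    out <- resolve_competition(two, land, p, seed = s)
    expect_equal(sum(out$eliminated), 1L)
    out$eliminated[1L]
  }, logical(1))
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(first_dies) - 0.5), 3 * se)
})

test_that("no two surviving colonies overlap after competition", {
  land <- flat_landscape(30)
  p <- tiny_params(n_side = 30, r_territory = 3)
  for (s in 1:10) {
    withr::with_seed(s, {
      k <- 25
      cells <- sample(900, k)
      cols <- tibble::tibble(
        colony = seq_len(k),
        row = (cells - 1) %/% 30 + 1L,
        col = (cells - 1) %% 30 + 1L,
        x = sample(6, k, replace = TRUE),
        coop_proportion = runif(k)
      )
    })
    out <- resolve_competition(cols, land, p, seed = s + 100)
    surv <- dplyr::filter(out, !eliminated)
    if (nrow(surv) > 1) {
      pr <- utils::combn(nrow(surv), 2)
      d <- torus_distance(surv$row[pr[1, ]], surv$col[pr[1, ]],
                          surv$row[pr[2, ]], surv$col[pr[2, ]], 30)
      expect_true(all(d > 2 * p$r_territory))
    }
  }
})

test_that("center-in-disk overlap uses the shorter reach", {
  land <- flat_landscape(20)
  pd <- tiny_params(r_territory = 2, overlap_rule = "disk-disk")
  pc <- tiny_params(r_territory = 2, overlap_rule = "center-in-disk")
  # distance 3: overlaps under disk-disk (<= 4) but not center-in-disk (<= 2)
  two <- tibble::tibble(colony = 1:2, row = c(5L, 5L), col = c(5L, 8L),
                        x = c(2L, 2L), coop_proportion = c(1, 1))
  expect_equal(sum(resolve_competition(two, land, pd, seed = 3)$eliminated), 1L)
  expect_equal(sum(resolve_competition(two, land, pc, seed = 3)$eliminated), 0L)
})

test_that("reproduction allocates equal shares per colony", {
  p <- tiny_params(p_mutate = 0)
  all_coop <- tibble::tibble(colony = 1:3, row = 1:3, col = 1:3,
                             x = c(2L, 5L, 1L), coop_proportion = 1)
  off <- reproduce(all_coop, p, seed = 1)
  expect_true(all(off$phenotype == "cooperative"))
  expect_equal(attr(off, "coop_share"), 1)

  # one all-cooperative colony + one aggressive singleton: share 1/2
  mixed <- tibble::tibble(colony = 1:2, row = 1:2, col = 1:2,
                          x = c(5L, 1L), coop_proportion = c(1, 0))
  counts <- vapply(1:2000, function(s) {
    off <- reproduce(mixed, p, seed = s)
    expect_equal(attr(off, "coop_share"), 0.5)
    sum(off$phenotype == "cooperative")
  }, numeric(1))
  se <- sqrt(p$m * 0.25) / sqrt(2000)
  expect_lt(abs(mean(counts) - p$m / 2), 3 * se)
})

test_that("full mutation scrambles offspring to a fair coin", {
  p <- tiny_params(p_mutate = 0.5, m = 400L)
  parents <- tibble::tibble(colony = 1L, row = 1L, col = 1L, x = 4L,
                            coop_proportion = 1)
  counts <- vapply(1:500, function(s) {
    sum(reproduce(parents, p, seed = s)$phenotype == "cooperative")
  }, numeric(1))
  se <- sqrt(400 * 0.25) / sqrt(500)
  expect_lt(abs(mean(counts) - 200), 3 * se)
})

test_that("extinction is an error in reproduce", {
  p <- tiny_params()
  gone <- tibble::tibble(colony = 1L, row = 1L, col = 1L, x = 2L,
                         coop_proportion = 1, eliminated = TRUE)
  expect_error(reproduce(gone, p, seed = 1), "extinct")
})
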