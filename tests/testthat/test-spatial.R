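# Quadrat-count statistics and the Monte Carlo CSR test.

test_that("density converts window area to hectares", {
  pp <- point_pattern(data.frame(x = runif(10, 0, 100), y = runif(10, 0, 100)),
                      c(0, 100, 0, 100))
  expect_equal(pattern_density(pp), 10)
  empty <- point_pattern(data.frame(x = numeric(0), y = numeric(0)),
                         c(0, 100, 0, 100))
  expect_equal(pattern_density(empty), 0)
  wide <- point_pattern(pp$points, c(0, 200, 0, 100))
  expect_equal(pattern_density(wide), 5)
  expect_error(point_pattern(data.frame(x = 1, y = 1), c(0, 0, 0, 1)),
               "positive area")
  expect_error(point_pattern(data.frame(x = 500, y = 1), c(0, 100, 0, 100)),
               "inside")
})

test_that("quadrat statistic matches an explicit point-in-rectangle oracle", {
  oracle <- function(pp, nx, ny) {
    w <- pp$window
    bx <- seq(w[1], w[2], length.out = nx + 1)
    by <- seq(w[3], w[4], length.out = ny + 1)
    counts <- matrix(0, ny, nx)
    for (i in seq_len(nrow(pp$points))) {
      x <- pp$points$x[i]; y <- pp$points$y[i]
      cx <- max(which(bx <= x + 1e-12)); cx <- min(cx, nx)
      cy <- max(which(by <= y + 1e-12)); cy <- min(cy, ny)
      counts[cy, cx] <- counts[cy, cx] + 1
    }
    e <- nrow(pp$points) / (nx * ny)
    sum((counts - e)^2 / e)
  }
  for (s in 1:20) {
    pp <- simulate_point_pattern("csr", n = 50, seed = s)
    expect_equal(quadrat_statistic(pp, 5, 4), oracle(pp, 5, 4),
                 tolerance = 1e-10)
    expect_equal(quadrat_statistic(pp, 3, 3), oracle(pp, 3, 3),
                 tolerance = 1e-10)
  }
})

test_that("balanced and concentrated patterns hit the closed-form extremes", {
  # 4 quadrats x 3 points each: statistic 0
  g <- expand.grid(x = c(12.5, 37.5, 62.5, 87.5), y = c(10, 50, 90))
  pp <- point_pattern(data.frame(x = rep(g$x, 1), y = g$y), c(0, 100, 0, 100))
  expect_equal(quadrat_statistic(pp, 4, 1), 0)
  # all n points in one of k quadrats: statistic n (k - 1)
  solid <- point_pattern(data.frame(x = rep(5, 12), y = rep(5, 12)),
                         c(0, 100, 0, 100))
  expect_equal(quadrat_statistic(solid, 5, 5), 12 * 24)
  expect_error(quadrat_statistic(solid, 1, 1), "two quadrats")
  none <- point_pattern(data.frame(x = numeric(0), y = numeric(0)),
                        c(0, 100, 0, 100))
  expect_error(quadrat_statistic(none, 2, 2), "no points")
})

test_that("boundary points land in exactly one quadrat", {
  pp <- point_pattern(data.frame(x = c(0, 50, 100), y = c(0, 50, 100)),
                      c(0, 100, 0, 100))
  # half-open cells: (0,0) -> lower-left, (50,50) and (100,100) both
  # upper-right (the window's top edge closes into the last quadrat)
  expect_equal(quadrat_statistic(pp, 2, 2),
               sum((c(1, 0, 0, 2) - 0.75)^2 / 0.75))
})

test_that("the Monte Carlo p-value attains its plus-one floor on extreme input", {
  solid <- point_pattern(data.frame(x = rep(1, 40), y = rep(1, 40)),
                         c(0, 100, 0, 100))
  out <- quadrat_mc_test(solid, 5, 5, n_sim = 1999, seed = 1)
  expect_equal(out$p_value, 1 / 2000)
  expect_equal(out$p_value, 0.0005)
  gl <- glance(out)
  expect_equal(gl$n_sim, 1999L)
  expect_s3_class(autoplot(out), "ggplot")
})

test_that("clustered patterns are rejected and CSR is not, typically", {
  clus <- simulate_point_pattern("clustered", n = 100, dispersal_sd = 2,
                                 seed = 4)
  out <- quadrat_mc_test(clus, 5, 5, n_sim = 199, seed = 5)
  expect_lte(out$p_value, 0.05)
  csr <- simulate_point_pattern("csr", n = 100, seed = 6)
  out2 <- quadrat_mc_test(csr, 5, 5, n_sim = 199, seed = 7)
  expect_gt(out2$p_value, 0.05)
})

test_that("the size scan runs one test per grid and flags consistency", {
  clus <- simulate_point_pattern("clustered", n = 80, dispersal_sd = 2,
                                 seed = 8)
  scan <- quadrat_size_scan(clus, list(c(2, 2), c(4, 4), c(5, 5)),
                            n_sim = 199, seed = 9)
  expect_equal(nrow(scan), 3L)
  expect_true(all(scan$p_value >= 1 / 200))
  expect_true(attr(scan, "consistent_departure"))
  single <- quadrat_size_scan(clus, list(c(4, 4)), n_sim = 199, seed = 10)
  expect_equal(nrow(single), 1L)
})

test_that("two-sided tests flag excessive regularity", {
  g <- expand.grid(x = seq(5, 95, by = 10), y = seq(5, 95, by = 10))
  regular <- point_pattern(g, c(0, 100, 0, 100))
  up <- quadrat_mc_test(regular, 5, 5, n_sim = 199, seed = 11)
  two <- quadrat_mc_test(regular, 5, 5, n_sim = 199, seed = 11,
                         alternative = "two.sided")
  expect_gt(up$p_value, 0.9)    # perfectly even: upper tail sees nothing
  expect_lt(two$p_value, 0.05)  # two-sided flags the regularity
})
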