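test_that("default two-way grid matches the published threshold table cell for cell", {
  grid <- two_way_grid()
  expected <- rbind(
    c(8750, 17500, 22750, 35000, 43750),
    c(16250, 32500, 42250, 65000, 81250),
    c(30000, 60000, 78000, 120000, 150000),
    c(45000, 90000, 117000, 180000, 225000)
  )
  expect_equal(unname(unclass(grid))[, ], expected)
  expect_identical(dim(grid), c(4L, 5L))
})

test_that("every grid cell equals decision_threshold on the same inputs", {
  costs <- c(120000, 500000, 910000)
  dps <- c(0.03, 0.11, 0.22)
  grid <- two_way_grid(costs, dps)
  for (i in seq_along(costs)) {
    for (j in seq_along(dps)) {
      expect_equal(unclass(grid)[i, j],
                   decision_threshold(dps[j], 0, costs[i]))
    }
  }
  # 1x1 grid is just the threshold
  expect_equal(unname(unclass(two_way_grid(600000, 0.13))[1, 1]), 78000)
})

test_that("grid cells are monotone along both axes and axes are validated", {
  grid <- unclass(two_way_grid())
  expect_true(all(apply(grid, 1, function(r) !is.unsorted(r))))
  expect_true(all(apply(grid, 2, function(cl) !is.unsorted(cl))))
  expect_error(two_way_grid(numeric(), 0.1), "non-empty")
  expect_error(two_way_grid(1000, numeric()), "non-empty")
  expect_error(two_way_grid(-5, 0.1), "non-negative")
  expect_error(two_way_grid(1000, 1.5), "\\[0, 1\\]")
})

test_that("high-risk directional robustness holds over severe/catastrophic tiers", {
  expect_true(directional_robustness())
  cells <- attr(directional_robustness(), "cells")
  expect_identical(dim(cells), c(2L, 4L))  # tiers 3-4 x dP >= 0.10
  expect_true(all(cells > 50000))
})

test_that("one-way sweep recomputes the full decision per substituted value", {
  base <- decision_inputs(50000, 0.20, 0.07, 600000)
  tab <- one_way(base, "c", c(600000, 800000))
  expect_equal(tab$threshold, c(78000, 104000))
  expect_identical(tab$verdict, rep("reconstruction_favored", 2))

  # sweeping delta_c across the threshold flips the verdict exactly once
  sweep <- one_way(base, "delta_c", seq(10000, 150000, by = 10000))
  v <- sweep$verdict
  flips <- sum(v[-1] != v[-length(v)])
  expect_identical(flips, 1L)
  expect_identical(v[1], "reconstruction_favored")
  expect_identical(v[length(v)], "closure_favored")

  # threshold strictly decreasing in p2 at fixed p1
  p2s <- seq(0.01, 0.15, by = 0.02)
  thr <- one_way(base, "p2", p2s)$threshold
  expect_true(all(diff(thr) < 0))
  expect_equal(thr, (0.20 - p2s) * 600000)

  expect_error(one_way(base, "gamma", 1), "one of")
  expect_error(one_way(base, "p2", 0.5), "no absolute risk reduction")
})

test_that("PSA with point masses reproduces the deterministic verdict", {
  run_point <- function(delta_c) {
    run_psa(psa_config(delta_c = delta_c, p1 = 0.20, p2 = 0.07, c = 600000,
                       n_samples = 500, seed = 9))
  }
  expect_equal(run_point(50000)$probability_favored, 1.0)
  expect_equal(run_point(200000)$probability_favored, 0.0)
})

test_that("PSA point-mass mixture matches exhaustive enumeration", {
  # two-point cost support sampled via two point-mass runs = full enumeration
  delta_c <- 78000
  support <- c(600000, 900000)     # thresholds 78000 (not favored), 117000
  enumerated <- mean(0.13 * support > delta_c)
  halves <- vapply(support, function(cc) {
    run_psa(psa_config(delta_c, 0.20, 0.07, cc, n_samples = 200,
                       seed = 4))$probability_favored
  }, numeric(1))
  expect_equal(mean(halves), enumerated)
})

test_that("uniform-cost PSA matches the closed-form exceedance probability", {
  # P(favored) = P(dp * C > delta_c) = P(C > 600000) = 0.5 under U(400k, 800k)
  cfg <- psa_config(delta_c = 78000, p1 = 0.20, p2 = 0.07,
                    c = c(400000, 800000), n_samples = 10000, seed = 42)
  res <- run_psa(cfg)
  se <- sqrt(0.5 * 0.5 / res$n_effective)
  expect_lt(abs(res$probability_favored - 0.5), 3 * se)

  # analytic check at an off-center threshold: P(C > 500000) = 0.75
  cfg2 <- psa_config(delta_c = 0.13 * 500000, p1 = 0.20, p2 = 0.07,
                     c = c(400000, 800000), n_samples = 10000, seed = 43)
  res2 <- run_psa(cfg2)
  expect_lt(abs(res2$probability_favored - 0.75),
            3 * sqrt(0.75 * 0.25 / res2$n_effective))
})

test_that("PSA is bit-reproducible per seed and leaves the caller RNG alone", {
  cfg <- psa_config(delta_c = 60000, p1 = c(0.15, 0.25), p2 = c(0.05, 0.10),
                    c = c(400000, 800000), n_samples = 2000, seed = 7)
  a <- run_psa(cfg); b <- run_psa(cfg)
  expect_identical(a, b)

  set.seed(123); before <- runif(5)
  set.seed(123); invisible(run_psa(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("probability favored is non-increasing in delta_c at fixed seed", {
  ladder <- seq(10000, 200000, by = 10000)
  probs <- vapply(ladder, function(dc) {
    run_psa(psa_config(dc, p1 = c(0.15, 0.25), p2 = c(0.05, 0.10),
                       c = c(400000, 800000), n_samples = 3000,
                       seed = 21))$probability_favored
  }, numeric(1))
  expect_true(all(diff(probs) <= 0))
  expect_true(probs[1] > probs[length(probs)])
})

test_that("P2 < P1 ordering is enforced by resampling and reported", {
  # overlapping ranges force rejections but remain samplable
  cfg <- psa_config(delta_c = 10000, p1 = c(0.10, 0.20), p2 = c(0.05, 0.18),
                    c = 500000, n_samples = 5000, seed = 5)
  res <- run_psa(cfg)
  expect_gt(res$rejection_rate, 0)
  expect_identical(res$n_effective, 5000L)
  # unsatisfiable point masses error with the rejection rate reported
  expect_error(
    run_psa(psa_config(10000, p1 = 0.10, p2 = 0.20, c = 500000,
                       n_samples = 100, seed = 5)),
    "rejection rate")
})

test_that("triangular sampling stays in range and centers on the midpoint", {
  cfg <- psa_config(delta_c = 50000, p1 = 0.20, p2 = 0.07,
                    c = c(400000, 800000), n_samples = 20000, seed = 31,
                    dist = "triangular")
  res <- run_psa(cfg)
  expect_true(res$threshold$quantiles[["2.5%"]] >= 0.13 * 400000)
  expect_true(res$threshold$quantiles[["97.5%"]] <= 0.13 * 800000)
  # symmetric triangular mean = midpoint threshold
  expect_equal(res$threshold$mean, 78000, tolerance = 0.01)
})

test_that("psa_config validates its inputs", {
  expect_error(psa_config(1, 0.2, 0.1, 1000, seed = 1, n_samples = 0),
               "at least 1")
  expect_error(psa_config(1, 1.5, 0.1, 1000, seed = 1), "\\[0, 1\\]")
  expect_error(psa_config(1, 0.2, 0.1, 1000), "seed")
  expect_error(psa_config(-1, 0.2, 0.1, 1000, seed = 1), "non-negative")
})
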