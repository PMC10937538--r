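test_that("intensity and focality metrics follow their definitions", {
  sys <- make_toy_system(L1 = c(1, -1))
  expect_equal(gamma_metric(sys, c(0, 0)), 0)
  expect_equal(gamma_metric(sys, c(2, -2)), 4)

  # M = 1, L2 y = 2, Gamma = 4  ->  Theta = 4 / (2 / 1) = 2
  sys1 <- make_toy_system(L1 = c(1, -1), L2 = c(0.5, 0))
  y <- c(2, -2)
  expect_equal(gamma_metric(sys1, y), 4)
  expect_equal(theta_metric(sys1, y), 4 / sqrt(sum((sys1$L2 %*% y)^2)))

  # a null-space montage with positive intensity has infinite focality
  sys2 <- make_toy_system(L1 = c(1, -1), L2 = c(1, 1))
  expect_equal(theta_metric(sys2, c(1, -1)), Inf)
  expect_equal(theta_metric(sys2, c(0, 0)), 0)
  expect_warning(th <- theta_metric(make_toy_system(L1 = c(1, -1)), c(1, -1)),
                 "M = 0")
  expect_equal(th, Inf)

  # positive scaling moves Gamma linearly and leaves Theta unchanged
  sys3 <- make_system(L = 8, P = 6, seed = 3, node = 2)
  set.seed(2)
  y3 <- rnorm(8); y3 <- y3 - mean(y3)
  expect_equal(gamma_metric(sys3, 3 * y3), 3 * gamma_metric(sys3, y3))
  expect_equal(theta_metric(sys3, 3 * y3), theta_metric(sys3, y3))
})

test_that("nnz channel counting thresholds against the dose", {
  expect_equal(nnz_channels(c(2, -2, 0, 0), mu = 4), 2)
  expect_equal(nnz_channels(rep(0, 8)), 0)
  expect_equal(nnz_channels(c(1, -1, 1e-12, 0), mu = 4,
                            threshold_fraction = 0), 3)
  expect_equal(nnz_channels(c(1, -1, 3e-3, 0), mu = 4), 2)
  expect_error(nnz_channels(c(1, -1), threshold_fraction = 1), "< 1")
})

test_that("solve_at returns coherent records across regimes", {
  sys <- make_toy_system(L1 = c(1, -1), amplitude = 3.85)
  res <- suppressWarnings(solve_at(sys, l1l1_config(0, 0, gamma = 2, mu = 4)))
  expect_equal(res$record$status, "optimal")
  # the bipolar solution fits x1 exactly: Gamma = ||x1||
  expect_equal(res$record$gamma_metric, 3.85, tolerance = 1e-6)

  # regularization-dominant limit: y -> 0, Gamma -> 0
  sysb <- make_system(L = 8, P = 6, seed = 3, node = 2)
  resb <- solve_at(sysb, l1l1_config(1e3, 0.5))
  expect_lt(abs(resb$record$gamma_metric), 1e-6)
  expect_equal(resb$record$nnz, 0)

  # dB coordinates are carried through
  res2 <- solve_at(sysb, l1l1_config(1e-3, 0.5), alpha_db = -60,
                   epsilon_db = -6.02)
  expect_equal(res2$record$alpha_db, -60)
})

test_that("every optimal montage satisfies the safety constraints", {
  sys <- make_system(L = 10, P = 8, seed = 19, node = 4)
  for (a in c(0, 1e-3)) {
    for (e in c(1e-6, 0.1, 1)) {
      res <- solve_at(sys, l1l1_config(a, e))
      if (res$record$status == "optimal") {
        expect_true(satisfies_safety(res$pattern, gamma = 2, mu = 4))
      }
    }
  }
})

test_that("lattice optima never beat the bipolar reciprocity ceiling", {
  sys <- make_system(L = 10, P = 8, seed = 29, node = 4)
  ceiling <- bipolar_maximizer(sys)$gamma_max
  set.seed(7)
  for (i in 1:10) {
    cfg <- l1l1_config(10^runif(1, -5, -1), 10^runif(1, -8, 0))
    res <- solve_at(sys, cfg)
    if (res$record$status == "optimal") {
      expect_lte(res$record$gamma_metric, ceiling + 1e-6)
    }
  }
})

test_that("metacriterion floor scales with fraction and dose", {
  sys <- make_toy_system(L1 = c(0.5, -0.3, 0.1))
  expect_equal(metacriterion_floor(sys, fraction = 1), 1.6)
  expect_equal(metacriterion_floor(sys, fraction = 0.75), 1.2)
  expect_equal(metacriterion_floor(sys, fraction = 0.75, mu = 8, gamma = 4),
               2.4)
  expect_error(metacriterion_floor(sys, fraction = 0), "positive")
})
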