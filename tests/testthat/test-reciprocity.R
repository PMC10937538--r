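test_that("back-projection arithmetic and the Gamma inner-product identity", {
  sys <- make_toy_system(L1 = c(1, -1))
  expect_equal(unname(back_projection(sys)), c(1, -1))

  sys2 <- make_system(L = 10, P = 8, seed = 13, node = 4)
  b <- back_projection(sys2)
  set.seed(1)
  for (i in 1:5) {
    y <- rnorm(10)
    expect_equal(gamma_metric(sys2, y), sum(b * y))
  }
  # an electrode with zero target response back-projects to zero
  sys3 <- make_toy_system(L1 = c(0.7, 0, -0.2))
  expect_equal(unname(back_projection(sys3))[2], 0)
})

test_that("restricted montages follow the printed normalization", {
  sys <- make_toy_system(L1 = c(0.5, -0.3, 0.1))
  r2 <- restricted_montage(sys, 2)
  expect_equal(r2$s_K, c(0.625, -0.375))
  expect_equal(r2$sigma_K, 0.8)
  expect_equal(sum(abs(r2$s_K)), 1)
  expect_equal(r2$gamma_K, 4 * 0.8 * (0.625^2 + 0.375^2))

  r1 <- restricted_montage(sys, 1)
  expect_equal(abs(r1$s_K), 1)
  expect_equal(r1$gamma_K, 4 * r1$sigma_K)

  # ||s_K||_1 = 1 for every K
  for (K in 1:3) {
    expect_equal(sum(abs(restricted_montage(sys, K)$s_K)), 1)
  }
})

test_that("gamma of the restricted montage equals mu * sigma_K * ||s_K||_2^2", {
  sys <- make_system(L = 12, P = 9, seed = 17, node = 5)
  for (K in c(2, 4, 6)) {
    r <- restricted_montage(sys, K, mu = 4)
    y <- numeric(12)
    y[r$electrodes] <- r$y_K
    expect_equal(gamma_metric(sys, y), r$gamma_K, tolerance = 1e-12)
  }
})

test_that("restricted-montage intensity is non-increasing in K", {
  # Gamma_K = mu * sum(v^2) / (||x1|| * sum(v)) over the K largest |v|:
  # appending a smaller response can only dilute the dose, so the K = 1
  # singleton (and, under zero-sum, the bipolar pair) carries the maximum.
  set.seed(5)
  for (trial in 1:20) {
    b <- rnorm(8)
    sys <- make_toy_system(L1 = b)
    gammas <- sapply(1:8, function(K) restricted_montage(sys, K)$gamma_K)
    expect_true(all(diff(gammas) <= 1e-12))
  }
})

test_that("bipolar maximizer arithmetic, ties, and homogeneity in mu", {
  sys <- make_toy_system(L1 = c(0.5, -0.3, 0.1))
  bp <- bipolar_maximizer(sys, mu = 4, gamma = 2)
  expect_equal(as.numeric(bp$pattern), c(2, -2, 0))
  expect_equal(bp$gamma_max, 1.6)
  expect_equal(sum(as.numeric(bp$pattern)), 0)

  # single nonzero entry pairs with a zero electrode
  sys1 <- make_toy_system(L1 = c(0.4, 0, 0))
  bp1 <- bipolar_maximizer(sys1, mu = 4)
  expect_equal(bp1$gamma_max, 2 * 0.4)
  expect_equal(sum(as.numeric(bp1$pattern)), 0)

  # degree-1 homogeneity in the dose
  sys2 <- make_system(L = 10, P = 8, seed = 23, node = 2)
  expect_equal(bipolar_maximizer(sys2, mu = 8, gamma = 4)$gamma_max,
               2 * bipolar_maximizer(sys2, mu = 4, gamma = 2)$gamma_max)
  expect_error(bipolar_maximizer(sys2, mu = 4, gamma = 1), "gamma >= mu / 2")
})

test_that("the bipolar pattern solves the intensity LP", {
  for (seed in c(41, 42, 43)) {
    sys <- make_system(L = 10, P = 8, seed = seed, node = 3)
    b <- back_projection(sys)
    bp <- bipolar_maximizer(sys)
    rep <- solve_lp(intensity_lp(b), solver_spec("primal-simplex"))
    expect_equal(rep$status, "optimal")
    expect_equal(-rep$objective, bp$gamma_max,
                 tolerance = 1e-10)
  }
})

test_that("dipolar targets make the first-two-entries rule and zero-sum rule coincide", {
  # tangentially oriented mid-depth targets whose two strongest
  # back-projections straddle zero (regression fixtures)
  fixtures <- list(list(L = 16, P = 12, seed = 3), list(L = 16, P = 12, seed = 6),
                   list(L = 16, P = 12, seed = 10), list(L = 64, P = 20, seed = 5),
                   list(L = 64, P = 20, seed = 6))
  for (fx in fixtures) {
    sys <- make_system(L = fx$L, P = fx$P, seed = fx$seed,
                       node = if (fx$L == 16) 2 else 5, dir = c(0, 1, 0))
    b <- back_projection(sys)
    ord <- order(abs(b), decreasing = TRUE)
    expect_lt(b[ord[1]] * b[ord[2]], 0)
    bp <- bipolar_maximizer(sys)
    expect_setequal(c(bp$anode, bp$cathode), ord[1:2])
  }
})

test_that("reciprocity report collates ordering, per-K table, and bipolar", {
  sys <- make_system(L = 10, P = 8, seed = 13, node = 4)
  rec <- reciprocity_report(sys, K_max = 5)
  expect_equal(nrow(rec$per_K), 5)
  expect_equal(rec$per_K$gamma_K[1], restricted_montage(sys, 1)$gamma_K)
  g <- glance(rec)
  expect_equal(g$gamma_max, rec$bipolar$gamma_max)
  expect_true(is.character(g$anode))
})
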