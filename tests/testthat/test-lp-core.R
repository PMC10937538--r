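test_that("LP dimensions follow the documented variable layout", {
  # L = 3 electrodes, single target node: T = 1, M = 2 (tangential rows)
  lf <- generate_sphere_leadfield(3, 1, seed = 1)
  sys <- build_focused_system(lf, target_spec(1, c(0, 0, 1)))
  expect_equal(nrow(sys$L2), 2)
  lp <- build_l1l1_lp(sys, l1l1_config(0.01, 0.5))
  expect_equal(length(lp$c), 2 * 3 + 1 + 2)            # 9 variables
  expect_equal(nrow(lp$A_ub), 2 * 1 + 2 * 2 + 2 * 3 + 1)  # 13 rows
  expect_equal(nrow(lp$A_eq), 1)
  expect_equal(as.numeric(lp$A_eq[1, ]), c(1, 1, 1, rep(0, 6)))

  # epsilon = 0 drops the nuisance floor; alpha = 0 zeroes the u costs
  lp0 <- build_l1l1_lp(sys, l1l1_config(0, 0))
  expect_equal(lp0$lb[lp0$layout$r], rep(0, 2))
  expect_equal(lp0$c[lp0$layout$u], rep(0, 3))
  expect_equal(lp0$c[c(lp0$layout$t, lp0$layout$r)], rep(1, 3))

  lp5 <- build_l1l1_lp(sys, l1l1_config(0.01, 0.5))
  expect_equal(lp5$lb[lp5$layout$r], rep(0.5, 2))
  expect_equal(lp5$ub[lp5$layout$y], rep(2, 3))
  expect_equal(lp5$lb[lp5$layout$y], rep(-2, 3))
})

test_that("objective_value evaluates the definition directly", {
  sys <- make_toy_system(L1 = c(1, -1), L2 = rbind(c(1, 0), c(0, 1)))
  # y = 0: |x1| + M * eps
  expect_equal(objective_value(sys, l1l1_config(0, 0.5), c(0, 0)),
               3.85 + 2 * 0.5)
  # perfect fit with vanishing nuisance
  sys2 <- make_toy_system(L1 = c(1, -1), L2 = c(1, 1))
  y <- c(3.85 / 2, -3.85 / 2)
  expect_equal(objective_value(sys2, l1l1_config(0, 0), y), 0)
  # regularization term uses zeta scaling
  expect_equal(objective_value(sys2, l1l1_config(0.1, 0), y),
               0.1 * sys2$zeta * 3.85)
  expect_error(objective_value(sys2, l1l1_config(0, 0), c(1, 2, 3)), "length")
})

test_that("the LP encoding agrees with direct objective evaluation at optima", {
  for (seed in c(4, 9)) {
    sys <- make_system(L = 6, P = 4, seed = seed, node = 2)
    cfg <- l1l1_config(alpha = 1e-3, epsilon = 0.2, gamma = 1.5, mu = 3)
    lp <- build_l1l1_lp(sys, cfg)
    rep <- solve_lp(lp, solver_spec("dual-simplex"))
    expect_equal(rep$status, "optimal")
    y <- extract_pattern(lp, rep)
    expect_equal(objective_value(sys, cfg, y), rep$objective,
                 tolerance = 1e-8)
    # majorants never undercut the direct value at any feasible point
    expect_lte(objective_value(sys, cfg, y), rep$objective + 1e-8)
  }
})

test_that("constraint support thresholds at epsilon * nu", {
  sys <- make_toy_system(L1 = c(1, -1),
                         L2 = rbind(c(1, 0), c(0, 1), c(15, 0)))
  nu <- sys$nu
  y <- c(0.1 * nu, 0.9 * nu)  # L2 y = nu * (0.1, 0.9, 1.5)
  expect_equal(constraint_support(sys, l1l1_config(0, 0.5), y), c(2L, 3L))
  expect_equal(constraint_support(sys, l1l1_config(0, 0), y), 1:3)
  expect_equal(constraint_support(sys, l1l1_config(0, 1), c(1e-9, 0)),
               integer())
})

test_that("regularization path: ||y||_1 is non-increasing in alpha", {
  sys <- make_system(L = 8, P = 5, seed = 6, node = 3)
  norms <- sapply(c(0, 1e-4, 1e-3, 1e-2, 1e-1), function(a) {
    res <- solve_at(sys, l1l1_config(a, 0.1))
    sum(abs(res$pattern))
  })
  expect_true(all(diff(norms) <= 1e-6))
  # strong regularization kills the montage entirely
  res <- solve_at(sys, l1l1_config(1e3, 0.1))
  expect_lt(sum(abs(res$pattern)), 1e-6)
})

test_that("lp debug serialization writes well-formed JSON", {
  sys <- make_toy_system(L1 = c(1, -1), L2 = c(0.5, 0.5))
  lp <- build_l1l1_lp(sys, l1l1_config(0.01, 0.1))
  f <- file.path(withr::local_tempdir(), "lp.json")
  lp_to_json(lp, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(back$c), lp$c, ignore_attr = TRUE)
  expect_equal(back$A_ub, lp$A_ub, ignore_attr = TRUE)
  expect_equal(unlist(back$b_ub), lp$b_ub, ignore_attr = TRUE)
})
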