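test_that("all algorithms find the unique zero-residual bipolar solution", {
  sys <- make_toy_system(L1 = c(1, -1), amplitude = 1)  # M = 0
  lp <- build_l1l1_lp(sys, l1l1_config(0, 0, gamma = 1, mu = 2))
  for (alg in all_algorithms) {
    rep <- solve_lp(lp, solver_spec(alg))
    expect_equal(rep$status, "optimal", info = alg)
    expect_equal(rep$objective, 0, tolerance = 1e-7, info = alg)
    y <- extract_pattern(lp, rep)
    expect_equal(as.numeric(y), c(0.5, -0.5), tolerance = 1e-6, info = alg)
  }
})

test_that("infeasible problems are reported, not mis-solved", {
  sys <- make_toy_system(L1 = c(1, -1), L2 = c(0.3, 0.2))
  lp <- build_l1l1_lp(sys, l1l1_config(0.01, 0.1))
  # contradictory bounds: detected by presolve in every backend
  lp_bad <- lp
  lp_bad$lb[1] <- 3; lp_bad$ub[1] <- 2
  for (alg in all_algorithms) {
    expect_equal(solve_lp(lp_bad, solver_spec(alg))$status, "infeasible",
                 info = alg)
  }
  # row-wise contradiction (x >= 0 with x <= -1)
  lp_row <- tesmontage:::new_lp_data(
    c(1), rbind(1), -1, matrix(0, 0, 1), numeric(0), 0, Inf, NULL)
  for (alg in c("primal-simplex", "dual-simplex")) {
    expect_equal(solve_lp(lp_row, solver_spec(alg))$status, "infeasible",
                 info = alg)
  }
})

test_that("iteration caps surface as iteration_limit", {
  sys <- make_system(L = 8, P = 5, seed = 6, node = 3)
  lp <- build_l1l1_lp(sys, l1l1_config(1e-3, 0.1))
  for (alg in all_algorithms) {
    rep <- solve_lp(lp, solver_spec(alg, max_iter = 1L))
    expect_equal(rep$status, "iteration_limit", info = alg)
    expect_true(is.na(rep$objective))
  }
})

test_that("unknown backends and algorithm mismatches are capability errors", {
  sys <- make_toy_system(L1 = c(1, -1))
  lp <- build_l1l1_lp(sys, l1l1_config(0, 0))
  expect_error(solve_lp(lp, solver_spec(backend = "mosek")), "no registered")
  expect_error(solve_lp(lp, solver_spec("dual-simplex",
                                        backend = "internal-ip")),
               "implements")
  expect_setequal(solver_registry()$algorithm, all_algorithms)
})

test_that("optimal reports pass an independent feasibility check", {
  fam <- lp_instance_family(4, n_electrodes = 10L, n_nodes = 8L, seed = 20L)
  for (lp in fam) {
    for (alg in all_algorithms) {
      rep <- solve_lp(lp, solver_spec(alg))
      expect_equal(rep$status, "optimal", info = alg)
      chk <- check_lp_solution(lp, rep$z)
      expect_lt(chk$max_violation, 1e-6)
    }
  }
})

test_that("compare_backends tabulates per-solve rows and flags disagreement", {
  fam <- lp_instance_family(2, n_electrodes = 8L, n_nodes = 6L, seed = 31L)
  specs <- list(solver_spec("interior-point"), solver_spec("dual-simplex"))
  tab <- compare_backends(fam[[1]], specs)
  expect_equal(nrow(tab), 2)

  tab2 <- compare_backends(fam, specs)
  expect_equal(nrow(tab2), 4)
  expect_false(any(tab2$disagrees))
  expect_true(all(tab2$status == "optimal"))

  # a capped solve shows up as a row, not an abort
  tab3 <- compare_backends(fam, list(solver_spec("dual-simplex"),
                                     solver_spec("primal-simplex",
                                                 max_iter = 1L)))
  expect_equal(sum(tab3$status == "iteration_limit"), 2)
  expect_error(compare_backends(fam, list()), "at least one")
})

test_that("all backends reproduce an external simplex on random inequality LPs", {
  # pracma::linprog (an unrelated simplex implementation) as the
  # independent oracle on tiny min c'x, Ax <= b, x >= 0 instances
  set.seed(77)
  for (trial in 1:5) {
    n <- 5; m <- 7
    A <- matrix(round(runif(m * n, -1, 2), 2), m, n)
    b <- round(runif(m, 0.5, 3), 2)
    cc <- round(runif(n, -2, 1), 2)
    lp <- tesmontage:::new_lp_data(cc, A, b, matrix(0, 0, n), numeric(0),
                                   rep(0, n), rep(Inf, n), NULL)
    oracle <- pracma::linprog(cc, A = A, b = b, maxiter = 500)$fval
    for (alg in all_algorithms) {
      rep <- solve_lp(lp, solver_spec(alg))
      expect_equal(rep$status, "optimal", info = alg)
      expect_equal(rep$objective, oracle, tolerance = 1e-6, info = alg)
    }
  }
})
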