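# Analytic concave quadratic over the dB plane, maximum at (a0, e0).
quad_fn <- function(a0 = -63, e0 = -41, ca = 0.01, ce = 0.004) {
  function(alpha_db, epsilon_db) {
    -ca * (alpha_db - a0)^2 - ce * (epsilon_db - e0)^2
  }
}

test_that("exhaustive search covers the full Cartesian lattice", {
  sp <- search_space(c(-10, 10), c(-10, 10), kappa = 2)
  ev <- function_evaluator(function(a, e) a + e)
  res <- exhaustive_search(sp, ev)
  expect_equal(res$evaluation_count, 4)
  expect_setequal(paste(res$trace$alpha_db, res$trace$epsilon_db),
                  c("-10 -10", "10 -10", "-10 10", "10 10"))
  # maximizer is the argmax over the evaluated records
  expect_equal(res$gamma_maximizer$gamma_metric, 20)
  expect_equal(c(res$gamma_maximizer$alpha_db, res$gamma_maximizer$epsilon_db),
               c(10, 10))

  sp15 <- search_space(kappa = 15)
  res15 <- exhaustive_search(sp15, function_evaluator(quad_fn()))
  expect_equal(res15$evaluation_count, 225)
  i <- which.max(res15$trace$gamma_metric)
  expect_equal(res15$gamma_maximizer$gamma_metric,
               res15$trace$gamma_metric[i])
})

test_that("direct search geometry: default polls sit on the axis midlines", {
  sp <- search_space()  # alpha [-100, -20], eps [-160, 0]
  ev <- function_evaluator(quad_fn())
  res <- direct_search(sp, ev, max_iter = 1)
  polls <- res$trace[2:5, ]
  expect_setequal(paste(polls$alpha_db, polls$epsilon_db),
                  c("-20 -80", "-100 -80", "-60 0", "-60 -160"))
})

test_that("direct search on a constant surface only halves the window", {
  sp <- search_space()  # spans 80 x 160 dB
  ev <- function_evaluator(function(a, e) 1)
  res <- direct_search(sp, ev)
  # windows (40, 80) halve 8 times before both drop below range/256
  expect_equal(res$extra$polls, 8)
  expect_equal(res$evaluation_count, 1 + 4 * 8)
  expect_equal(res$extra$pivot, c(-60, -80))
})

test_that("direct search converges into the terminal window on a concave quadratic", {
  sp <- search_space()
  f <- quad_fn(a0 = -57.3, e0 = -88.8)
  res <- direct_search(sp, function_evaluator(f), max_iter = 200)
  wmin <- c(80, 160) / 256
  expect_lt(abs(res$extra$pivot[1] - (-57.3)), wmin[1])
  expect_lt(abs(res$extra$pivot[2] - (-88.8)), wmin[2])
  # pivot is the best evaluated point
  expect_equal(f(res$extra$pivot[1], res$extra$pivot[2]),
               max(res$trace$gamma_metric))
})

test_that("recursive search renests the grid and keeps its workload contract", {
  sp <- search_space()
  f <- function_evaluator(quad_fn())
  for (K in c(3, 5, 7, 9)) {
    res <- recursive_search(sp, f, window = K, levels = 3)
    expect_equal(res$evaluation_count, 3 * K^2)
  }
  # single level reproduces the exhaustive lattice point set
  r1 <- recursive_search(sp, f, window = 5, levels = 1)
  ex <- exhaustive_search(search_space(kappa = 5), f)
  expect_setequal(paste(r1$trace$alpha_db, r1$trace$epsilon_db),
                  paste(ex$trace$alpha_db, ex$trace$epsilon_db))
  expect_equal(r1$gamma_maximizer$gamma_metric,
               ex$gamma_maximizer$gamma_metric)
})

test_that("recursive refinement is monotone and lands within a final grid step", {
  sp <- search_space()
  f <- quad_fn(a0 = -66.1, e0 = -47.9)
  res <- recursive_search(sp, function_evaluator(f), window = 5, levels = 3)
  bests <- tapply(res$trace$gamma_metric, res$trace$level, max)
  expect_true(all(diff(cummax(bests)) >= 0))
  expect_true(all(diff(bests) >= -1e-12))
  step_a <- diff(range(res$extra$final_alphas)) / 4
  step_e <- diff(range(res$extra$final_epss)) / 4
  expect_lt(abs(res$gamma_maximizer$alpha_db - (-66.1)), step_a + 1e-9)
  expect_lt(abs(res$gamma_maximizer$epsilon_db - (-47.9)), step_e + 1e-9)
})

test_that("focality maximizers honor the intensity floor or report empty", {
  # records where gamma and theta disagree: theta peaks where gamma is low
  ev <- function(alpha_db, epsilon_db) {
    tibble::tibble(alpha_db = alpha_db, epsilon_db = epsilon_db,
                   alpha = NA_real_, epsilon = NA_real_,
                   gamma_metric = -alpha_db / 100,
                   theta_metric = alpha_db / 100 + 2,
                   objective = NA_real_, nnz = NA_integer_,
                   status = "optimal")
  }
  sp <- search_space(c(-100, -20), c(-10, 0), kappa = 3)
  res <- exhaustive_search(sp, ev, gamma_floor = 0.5)
  # floor excludes alpha_db > -50, where theta would otherwise peak
  expect_gte(res$theta_maximizer$gamma_metric, 0.5)
  expect_equal(res$theta_maximizer$alpha_db, -60)

  res_none <- exhaustive_search(sp, ev, gamma_floor = 2)
  expect_null(res_none$theta_maximizer)
  expect_false(is.null(res_none$gamma_maximizer))
})

test_that("evaluator call counting matches the logged evaluation counts", {
  sys <- make_system(L = 6, P = 4, seed = 8, node = 2)
  ev <- l1l1_evaluator(sys)
  sp <- search_space(kappa = 3)
  res <- exhaustive_search(sp, ev)
  expect_equal(evaluator_calls(ev), 9)
  expect_equal(res$evaluation_count, 9)
  expect_length(evaluator_patterns(ev), 9)
})

test_that("lattice results tidy and glance cleanly", {
  f <- function_evaluator(quad_fn())
  res <- exhaustive_search(search_space(kappa = 3), f)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 9)
  g <- glance(res)
  expect_equal(g$evaluations, 9)
  expect_equal(g$method, "exhaustive")
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
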