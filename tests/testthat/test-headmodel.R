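test_that("monopole kernel matches direct arithmetic and its symmetries", {
  # node below a vertex electrode: z-component (0.5 - 1) / (4 pi 0.5^3)
  k <- tesmontage:::monopole_kernel(c(0, 0, 0.5), c(0, 0, 1))
  expect_equal(k[3], -0.5 / (4 * pi * 0.125), tolerance = 1e-12)
  expect_equal(k[3], -0.31830989, tolerance = 1e-7)
  expect_equal(k[1:2], c(0, 0))

  # electrodes at +/- z seen from the origin: antisymmetric under z-flip
  up <- tesmontage:::monopole_kernel(c(0, 0, 0), c(0, 0, 1))
  dn <- tesmontage:::monopole_kernel(c(0, 0, 0), c(0, 0, -1))
  expect_equal(up, -dn)
  expect_equal(up[1:2], c(0, 0))

  # magnitude strictly decays with distance along a collinear probe line
  e <- c(0, 0, 1)
  mags <- sapply(seq(0.8, 0, by = -0.2), function(z) {
    sqrt(sum(tesmontage:::monopole_kernel(c(0, 0, z), e)^2))
  })
  expect_true(all(diff(mags) < 0))
})

test_that("lead field generation is deterministic and obeys its invariants", {
  lf1 <- generate_sphere_leadfield(8, 10, seed = 42)
  lf2 <- generate_sphere_leadfield(8, 10, seed = 42)
  expect_identical(lf1$matrix, lf2$matrix)
  expect_identical(lf1$node_positions, lf2$node_positions)
  lf3 <- generate_sphere_leadfield(8, 10, seed = 43)
  expect_false(identical(lf1$matrix, lf3$matrix))

  expect_equal(nrow(lf1$matrix), 3 * 10)
  expect_equal(ncol(lf1$matrix), 8)
  expect_true(all(is.finite(lf1$matrix)))
  expect_equal(sqrt(rowSums(lf1$electrode_positions^2)), rep(1, 8),
               tolerance = 1e-9)
  expect_true(all(sqrt(rowSums(lf1$node_positions^2)) <= lf1$inner_radius))

  # columns carry the globally scaled kernel of their electrode
  p <- lf1$node_positions[4, ]
  e <- lf1$electrode_positions[2, ]
  expect_equal(lf1$matrix[10:12, 2],
               tesmontage:::KERNEL_SCALE * tesmontage:::monopole_kernel(p, e),
               ignore_attr = TRUE)
})

test_that("the built-in cap bounds electrode count and labels the 10-20 core", {
  expect_error(generate_sphere_leadfield(129, 5, seed = 1), "128")
  expect_error(ten_ten_cap(1), "at least 2")
  cap <- ten_ten_cap(21)
  expect_true(all(c("Cz", "Fpz", "Oz", "C3", "C4") %in% cap$label))
  expect_equal(nrow(ten_ten_cap(128)), 128)
  expect_false(anyDuplicated(ten_ten_cap(128)$label) > 0)
})

test_that("electrode restriction keeps geometry and labels aligned", {
  lf <- generate_sphere_leadfield(10, 6, seed = 7)
  sub <- restrict_leadfield(lf, c(2L, 5L, 9L))
  expect_equal(ncol(sub$matrix), 3)
  expect_equal(sub$electrode_labels, lf$electrode_labels[c(2, 5, 9)])
  expect_equal(sub$matrix, lf$matrix[, c(2, 5, 9)],
               ignore_attr = TRUE)
  expect_equal(restrict_leadfield(lf, lf$electrode_labels[c(2, 5, 9)])$matrix,
               sub$matrix)
  expect_error(restrict_leadfield(lf, 11L), "unknown")
  expect_error(restrict_leadfield(lf, 2L), "at least 2")
})
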