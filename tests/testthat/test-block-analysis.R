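test_that("whole-box blocks return the exact species totals", {
  cfg <- generate_ideal_binary(30, 20, box_edge = 6, seed = 71)
  counts <- sample_block_counts(cfg, lambda = 1, n_blocks = 10, seed = 72)
  expect_true(all(counts$A == 30))
  expect_true(all(counts$B == 20))
  ex <- exhaustive_block_counts(cfg, lambda = 1, grid_spacing = 2)
  expect_true(all(ex$A == 30 & ex$B == 20))
})

test_that("a single centred particle is found in a lambda^3 fraction of blocks", {
  cfg <- configuration(matrix(c(5, 5, 5), 1), box_edge = 10)
  ex <- exhaustive_block_counts(cfg, lambda = 0.5, grid_spacing = 0.25)
  expect_true(all(ex$A %in% c(0L, 1L)))
  expect_equal(mean(ex$A), 0.125, tolerance = 0.02)
  rnd <- sample_block_counts(cfg, lambda = 0.5, n_blocks = 20000, seed = 73)
  expect_equal(mean(rnd$A), 0.125, tolerance = 0.05)
})

test_that("blocks wrap across the periodic boundary", {
  # particle at the origin corner; a block anchored near the far corner
  # with wrapping must still contain it
  cfg <- configuration(matrix(c(0.1, 0.1, 0.1), 1), box_edge = 10)
  counts <- blockfluct:::block_counts_at(
    cfg, origins = matrix(c(9.5, 9.5, 9.5), 1), edges = 2
  )
  expect_equal(unname(counts[1, "A"]), 1L)
})

test_that("lambda validation rejects out-of-range block sizes", {
  cfg <- generate_ideal_gas(10, 5, seed = 74)
  expect_error(sample_block_counts(cfg, lambda = 0, n_blocks = 5, seed = 1),
               "lambda")
  expect_error(sample_block_counts(cfg, lambda = 1.2, n_blocks = 5, seed = 1),
               "lambda")
  expect_error(exhaustive_block_counts(cfg, lambda = 0.5, grid_spacing = 2),
               "grid_spacing")
})

test_that("fluctuation curve matches the ideal-gas closed form", {
  traj <- ideal_gas_trajectory(150, nA = 1000, box_edge = 10, seed = 75)
  grid <- c(0.1, 0.2, 0.35, 0.5, 0.7, 0.85, 1)
  cv <- fluctuation_curve(traj, lambda_grid = grid,
                          n_blocks_per_frame = 100, seed = 76)
  expected <- 1 - grid^3
  dev <- abs(cv$chi - expected)
  expect_true(all(dev[-length(grid)] < 3 * cv$stderr[-length(grid)]))
  # closed box: zero exactly, not approximately
  expect_identical(cv$chi[cv$lambda == 1], 0)
  expect_identical(cv$stderr[cv$lambda == 1], 0)
})

test_that("random-origin and exhaustive-grid moments agree on frozen frames", {
  cfg <- generate_ideal_gas(800, box_edge = 10, seed = 77)
  lam <- 0.4
  rnd <- sample_block_counts(cfg, lambda = lam, n_blocks = 4000, seed = 78)
  ex <- exhaustive_block_counts(cfg, lambda = lam, grid_spacing = 0.4)
  m_r <- mean(rnd$A); m_e <- mean(ex$A)
  se_r <- sd(rnd$A) / sqrt(nrow(rnd))
  # the exhaustive grid is (almost) the exact estimand on this frame
  expect_lt(abs(m_r - m_e), 3 * se_r + 0.05)
  v_r <- mean(rnd$A^2) - m_r^2
  v_e <- mean(ex$A^2) - m_e^2
  se_v <- sd((rnd$A - m_r)^2) / sqrt(nrow(rnd))
  expect_lt(abs(v_r - v_e), 3 * se_v + 0.5)
})

test_that("KBI curves of an ideal binary mixture vanish as they must", {
  traj <- ideal_gas_trajectory(150, nA = 500, nB = 500, box_edge = 10,
                               seed = 79)
  grid <- c(0.25, 0.4, 0.6, 1)
  kc <- kbi_curve(traj, lambda_grid = grid, n_blocks_per_frame = 200,
                  seed = 80)
  rhoA <- 0.5
  ab <- kc[kc$i == "A" & kc$j == "B" & kc$lambda < 1, ]
  expect_true(all(abs(ab$G) < 3 * ab$stderr + 1e-8))
  aa <- kc[kc$i == "A" & kc$j == "A" & kc$lambda < 1, ]
  expect_true(all(abs(aa$G - (-aa$lambda^3 / rhoA)) < 3 * aa$stderr + 1e-8))
  # closed-box limit of the estimator: G_ii(1) = -1/rho_i exactly
  aa1 <- kc$G[kc$i == "A" & kc$j == "A" & kc$lambda == 1]
  expect_equal(aa1, -1 / rhoA, tolerance = 1e-12)
  ab1 <- kc$G[kc$i == "A" & kc$j == "B" & kc$lambda == 1]
  expect_equal(ab1, 0, tolerance = 1e-12)
})

test_that("KBI estimator is symmetric and improves with more blocks", {
  traj <- ideal_gas_trajectory(40, nA = 300, nB = 200, box_edge = 8,
                               seed = 81)
  kc <- kbi_curve(traj, lambda_grid = c(0.3, 0.5), n_blocks_per_frame = 100,
                  seed = 82)
  # only unordered pairs are stored; the estimator is symmetric by
  # construction (same pooled <Ni Nj> samples)
  expect_setequal(unique(paste0(kc$i, kc$j)), c("AA", "AB", "BB"))

  kc2 <- kbi_curve(traj, lambda_grid = c(0.3, 0.5),
                   n_blocks_per_frame = 800, seed = 83)
  expect_lt(mean(kc2$stderr), mean(kc$stderr))
})

test_that("empty or invalid analysis inputs error cleanly", {
  traj <- ideal_gas_trajectory(3, nA = 50, box_edge = 5, seed = 84)
  expect_error(fluctuation_curve(traj, lambda_grid = numeric(0), seed = 1),
               "empty")
  expect_error(fluctuation_curve(traj, lambda_grid = c(0.5, 2), seed = 1),
               "lambda")
})
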