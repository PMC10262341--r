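test_that("the four-sequence worked example is reproduced", {
  opt <- optimize_allocation(sw_design(4, rho = 0.4, r = 0))
  expect_equal(unname(round(opt$p_star, 2)), c(0.33, 0.17, 0.17, 0.33))
  expect_true(opt$converged)
  # reported optimum equals the variance recomputed at p*
  expect_equal(opt$variance,
               treatment_variance(opt$p_star, sw_design(4, 0.4, 0)),
               tolerance = 1e-14)
  expect_equal(sum(opt$p_star), 1, tolerance = 1e-8)
})

test_that("box-constrained optimization lands exactly on active bounds", {
  opt <- optimize_allocation(sw_design(4, rho = 0.2, r = 0),
                             lower = 0.15, upper = 0.35)
  expect_equal(unname(opt$p_star), c(0.35, 0.15, 0.15, 0.35), tolerance = 1e-8)
  expect_equal(opt$active_bounds$sequence, 1:4)
  expect_equal(opt$active_bounds$side, c("upper", "lower", "lower", "upper"))
})

test_that("optimizer at least matches the exhaustive lattice oracle", {
  for (J in c(3, 4)) {
    for (rho in c(0.1, 0.5, 0.9)) {
      for (r in c(0, 0.2)) {
        d <- sw_design(J, rho, r)
        opt <- optimize_allocation(d, n_starts = 3, seed = 11)
        orc <- grid_oracle(d, resolution = 0.02)
        expect_lte(opt$variance, orc$variance + 1e-9)
        expect_lt(max(abs(opt$p_star - orc$p)), 0.02 + 1e-9)
      }
    }
  }
})

test_that("optimal allocations are symmetric without attrition", {
  for (J in 3:6) {
    opt <- optimize_allocation(sw_design(J, rho = 0.5, r = 0), n_starts = 3)
    p <- unname(opt$p_star)
    expect_lt(max(abs(p - rev(p))), 1e-3)
  }
})

test_that("edge sequences get the highest proportions without attrition", {
  for (rho in c(0.1, 0.5, 0.9)) {
    p <- unname(optimize_allocation(sw_design(4, rho, 0), n_starts = 3)$p_star)
    expect_true(which.max(p) == 1 || abs(max(p) - p[1]) < 1e-3)
  }
})

test_that("attrition tilts the optimum toward early-switching sequences", {
  for (r in c(0.05, 0.2)) {
    for (rho in c(0.2, 0.5, 0.8)) {
      p <- unname(optimize_allocation(sw_design(4, rho, r), n_starts = 3)$p_star)
      expect_gt(p[1], p[4])
    }
  }
})

test_that("optimization is deterministic for a fixed seed", {
  d <- sw_design(5, rho = 0.3, r = 0.1)
  a <- optimize_allocation(d, n_starts = 5, seed = 99)
  b <- optimize_allocation(d, n_starts = 5, seed = 99)
  expect_identical(a$p_star, b$p_star)
  expect_identical(a$variance, b$variance)
})

test_that("degenerate and infeasible bound sets are handled", {
  d <- sw_design(3, rho = 0.4)
  # bounds collapsing to a single point: that point is returned
  opt <- optimize_allocation(d, lower = c(0.5, 0.3, 0.2),
                             upper = c(0.5, 0.3, 0.2))
  expect_equal(unname(opt$p_star), c(0.5, 0.3, 0.2), tolerance = 1e-8)
  expect_error(optimize_allocation(d, lower = 0.4), "infeasible")
  expect_error(optimize_allocation(d, upper = 0.2), "infeasible")
  expect_error(optimize_allocation(d, lower = 0.3, upper = 0.2), "bounds")
})

test_that("the lattice oracle validates its inputs and honours its cap", {
  d <- sw_design(3, rho = 0.5)
  expect_error(grid_oracle(d, resolution = 0.03), "resolution")
  expect_error(grid_oracle(d, resolution = 0.01, max_points = 10), "max_points")
  # two sequences: a 1-D scan over p_1
  d2 <- sw_design(2, rho = 0.5)
  orc <- grid_oracle(d2, resolution = 0.01)
  opt <- optimize_allocation(d2, n_starts = 3)
  expect_lte(opt$variance, orc$variance + 1e-9)
  expect_lt(abs(opt$p_star[1] - orc$p[1]), 0.01 + 1e-9)
  # bounds restrict the search
  orc_b <- grid_oracle(d, lower = 0.3, resolution = 0.05)
  expect_true(all(orc_b$p >= 0.3 - 1e-12))
})
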