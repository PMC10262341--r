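test_that("largest-remainder apportionment conserves the total", {
  expect_equal(apportion(c(0.33, 0.17, 0.17, 0.33), 100), c(33L, 17L, 17L, 33L))
  expect_equal(apportion(rep(1 / 3, 3), 100), c(34L, 33L, 33L))  # tie to lowest index
  set.seed(3)
  for (k in 1:10) {
    J <- sample(2:6, 1)
    p <- rexp(J); p <- p / sum(p)
    n <- sample(10:500, 1)
    a <- apportion(p, n)
    expect_equal(sum(a), n)
    expect_true(all(abs(a - p * n) < 1))
  }
})

test_that("simulated trials respect the design contract", {
  d <- sw_design(3, rho = 0.5, r = 0)
  dat <- simulate_trial(d, uniform_allocation(3), 30, seed = 1)
  expect_true(all(dat$observed))                      # r = 0: complete data
  expect_equal(nrow(dat), 30 * d$T)
  # treatment is a deterministic function of (sequence, period)
  L <- sequence_layout(3)
  expect_equal(dat$treatment, L[cbind(dat$sequence, dat$period)])

  d2 <- sw_design(3, rho = 0.5, r = 0.2)
  a <- simulate_trial(d2, uniform_allocation(3), 500, seed = 42)
  b <- simulate_trial(d2, uniform_allocation(3), 500, seed = 42)
  expect_identical(a, b)                              # determinism
  # monotone dropout, everyone observed at period 1
  obs <- matrix(a$observed[order(a$individual_id, a$period)], ncol = d2$T,
                byrow = TRUE)
  expect_true(all(obs[, 1]))
  expect_true(all(apply(obs, 1, function(o) all(diff(o) <= 0))))
  expect_true(all(is.na(a$outcome[!a$observed])))
  expect_warning(simulate_trial(d, c(0.98, 0.01, 0.01), 30, seed = 1),
                 "degenerate")
})

test_that("realized dropout fractions converge to the attrition weights", {
  d <- sw_design(3, rho = 0.5, r = 0.2)
  dat <- simulate_trial(d, uniform_allocation(3), 1e5, seed = 10)
  t_last <- tapply(dat$period[dat$observed], dat$individual_id[dat$observed], max)
  freq <- tabulate(t_last, nbins = d$T) / 1e5
  expect_lt(max(abs(freq - attrition_weights(d))), 0.01)
})

test_that("a null treatment effect leaves no intervention-control difference", {
  d <- sw_design(3, rho = 0.3, r = 0)
  dat <- simulate_trial(d, uniform_allocation(3), 3000, gamma = 0, seed = 2)
  diff_means <- mean(dat$outcome[dat$treatment == 1]) -
    mean(dat$outcome[dat$treatment == 0])
  expect_lt(abs(diff_means), 4 / sqrt(3000))
})

test_that("the GLS fit interpolates noiseless data exactly", {
  d <- sw_design(3, rho = 0.4, r = 0, sigma2 = 1e-12)
  tau <- c(0.5, -0.3, 0.8)
  dat <- simulate_trial(d, uniform_allocation(3), 12, beta = 2, tau = tau,
                        gamma = 1.5, seed = 4)
  fit <- fit_gls(dat, d)
  expect_equal(unname(fit$theta_hat), c(2, tau, 1.5), tolerance = 1e-6)
})

test_that("complete-data GLS matches the textbook whitened-OLS oracle", {
  d <- sw_design(3, rho = 0.6, r = 0, sigma2 = 2)
  dat <- simulate_trial(d, c(0.5, 0.25, 0.25), 40, beta = 1,
                        tau = c(0.2, 0.1, -0.1), gamma = 0.7, seed = 8)
  fit <- fit_gls(dat, d)
  expect_equal(unname(fit$theta_hat), oracle_gls_complete(dat, 3, 0.6, 2),
               tolerance = 1e-10)
})

test_that("the fitted covariance equals the realized-count information inverse", {
  d <- sw_design(3, rho = 0.5, r = 0.25)
  dat <- simulate_trial(d, uniform_allocation(3), 90, seed = 6)
  fit <- fit_gls(dat, d)
  V <- exp_decay_covariance(d)
  M <- matrix(0, d$T + 1, d$T + 1)
  for (j in 1:3) {
    X <- oracle_X(j, 3)
    for (t in 1:d$T) {
      if (fit$n_jt[j, t] == 0) next
      Xt <- X[1:t, , drop = FALSE]
      M <- M + fit$n_jt[j, t] * t(Xt) %*% solve(V[1:t, 1:t, drop = FALSE]) %*% Xt
    }
  }
  expect_equal(unname(fit$cov_theta), solve(M), tolerance = 1e-10)
})

test_that("non-monotone observation patterns are refused", {
  d <- sw_design(2, rho = 0.5)
  dat <- simulate_trial(d, uniform_allocation(2), 10, seed = 1)
  dat$observed[dat$individual_id == 1 & dat$period == 2] <- FALSE
  dat$outcome[dat$individual_id == 1 & dat$period == 2] <- NA
  expect_error(fit_gls(dat, d), "monotone")
})

test_that("trial data round-trip through long-format CSV", {
  d <- sw_design(3, rho = 0.5, r = 0.3)
  dat <- simulate_trial(d, uniform_allocation(3), 25, gamma = 1, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(dat, path)
  back <- read_trial_csv(path)
  expect_equal(back$outcome, dat$outcome)
  expect_equal(back$observed, dat$observed)
  expect_equal(back$individual_id, dat$individual_id)
  # header is present and missing outcomes are empty fields
  first <- readLines(path, n = 2)
  expect_match(first[1], "individual_id.*sequence.*period.*treatment.*outcome.*observed")
  fit1 <- fit_gls(dat, d)
  fit2 <- fit_gls(back, d)
  expect_equal(fit1$theta_hat, fit2$theta_hat, tolerance = 1e-12)
})

test_that("monte_carlo_variance enforces a minimum replicate count", {
  d <- sw_design(3, rho = 0.4)
  expect_error(monte_carlo_variance(d, uniform_allocation(3), 60, n_reps = 10),
               "n_reps")
})

test_that("the empirical variance tracks the analytic one", {
  d <- sw_design(3, rho = 0.4, r = 0)
  mc <- monte_carlo_variance(d, uniform_allocation(3), 120, gamma = 0.5,
                             n_reps = 400, seed = 21)
  expect_true(mc$agree)
  # unbiasedness of gamma_hat
  se_mean <- sqrt(mc$analytic_var / mc$n_reps)
  expect_lt(abs(mc$mean_gamma_hat - 0.5), 3 * se_mean)
  # attrition increases the empirical variance
  mc_r <- monte_carlo_variance(sw_design(3, 0.4, 0.2), uniform_allocation(3),
                               120, gamma = 0.5, n_reps = 400, seed = 21)
  expect_gt(mc_r$empirical_var, mc$empirical_var)
})
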