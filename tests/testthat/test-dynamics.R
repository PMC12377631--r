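test_that("the dimensionless field matches direct substitution", {
  dp <- dimensionless_params(1, 0.9, 0.788)
  expect_equal(lv_rhs_dimensionless(0, 0, dp), c(0, 0))
  expect_equal(lv_rhs_dimensionless(1, 0, dp), c(0, 0))
  expect_equal(lv_rhs_dimensionless(0.5, 0.5, dp),
               c(0.5 - 0.25 - 0.25, 0.45 - 0.25 - 0.197),
               tolerance = 1e-12)
})

test_that("the original field handles every therapy mode and reduces at D = 0", {
  p <- fx$regime4$kinetics
  expect_equal(lv_rhs_original(p$Kx, 0, p), c(0, 0))
  modes <- list(
    therapy_spec("proportional_constant", D = 0, beta_x = 0.1, beta_y = 0.01),
    therapy_spec("additive_constant", D = 0, beta_y = -0.025),
    therapy_spec("periodic_additive", D = 0, beta_y = -0.025, omega = 1))
  for (th in modes)
    expect_equal(lv_rhs_original(0.3, 0.4, p, th), lv_rhs_original(0.3, 0.4, p))
  # periodic forcing vanishes at t = 0 since 1 - cos(0) = 0
  thp <- therapy_spec("periodic_additive", D = 2, beta_y = -0.025, omega = 3)
  expect_equal(lv_rhs_original(0.3, 0.4, p, thp, t = 0),
               lv_rhs_original(0.3, 0.4, p))
  # proportional mode at the tumor extinction dose: x strictly decreasing
  beta_x <- 0.05
  thx <- therapy_spec("proportional_constant", D = p$rx / beta_x,
                      beta_x = beta_x, beta_y = 0)
  for (x in c(0.1, 0.5, 1.5))
    expect_lt(lv_rhs_original(x, 0, p, thx)[1], 0)
})

test_that("simulation holds equilibria and reaches the coexistence point", {
  dp <- fx$regime2$dimensionless
  eq <- equilibria(dp)
  # start exactly at P4: stays there
  tr <- lv_simulate(eq$P4$location, dp, t_end = 100, n_out = 11)
  expect_lt(max(abs(tr$u - eq$P4$location[1])), 1e-7)
  expect_lt(max(abs(tr$v - eq$P4$location[2])), 1e-7)
  # interior start converges to P4 (closed-form nullcline solution)
  tr2 <- lv_simulate(c(0.9, 0.1), dp, t_end = 2000, n_out = 21)
  expect_equal(as.numeric(tr2[nrow(tr2), 2:3]),
               c(0.1 / 0.212, 0.112 / 0.212), tolerance = 1e-4)
  # regime I: trajectories converge to P2 = (0, d)
  dp1 <- fx$regime1$dimensionless
  tr3 <- lv_simulate(c(0.7, 0.2), dp1, t_end = 3000, n_out = 11)
  expect_equal(as.numeric(tr3[nrow(tr3), 2:3]), c(0, 0.75),
               tolerance = 1e-5)
})

test_that("simulated states never leave the positive quadrant materially", {
  set.seed(11)
  worst <- 0
  for (i in 1:250) {
    dp <- dimensionless_params(runif(1, 0.3, 2), runif(1, 0.3, 1.6),
                               runif(1, 0.3, 1.6))
    s0 <- runif(2, 0, 1.5)
    tr <- lv_simulate(s0, dp, t_end = 50, n_out = 26)
    worst <- min(worst, min(tr$u), min(tr$v))
  }
  expect_gt(worst, -1e-8)
})

test_that("the capacity simplex is invariant for strictly valid parameters", {
  # the shared-capacity reading x + gamma*y <= K requires a common
  # carrying capacity (K = Kx = Ky) and non-negative kill coefficients,
  # i.e. alpha_xy >= rx/K and alpha_yx >= ry/K
  set.seed(12)
  for (i in 1:40) {
    K <- runif(1, 0.5, 3)
    rx <- runif(1, 0.05, 0.3); ry <- runif(1, 0.05, 0.3)
    p <- lv_params(rx, ry, K, K,
                   alpha_xy = runif(1, 1, 3) * rx / K,
                   alpha_yx = runif(1, 1, 3) * ry / K, strict = TRUE)
    lam <- runif(1, 0.05, 0.95); mix <- runif(1, 0.05, 0.95)
    s0 <- c(lam * mix * K, lam * (1 - mix) * K / p$gamma)  # x + gamma y < K
    tr <- lv_simulate(s0, p, t_end = 400, n_out = 101)
    expect_lte(max(tr$x + p$gamma * tr$y), K * (1 + 1e-6))
  }
})

test_that("proportional therapy equals the rescaled unperturbed system", {
  p <- fx$regime4$kinetics
  D <- 0.4; beta_x <- 0.05; beta_y <- 0.01
  th <- therapy_spec("proportional_constant", D = D, beta_x = beta_x,
                     beta_y = beta_y)
  rx_e <- p$rx - D * beta_x; ry_e <- p$ry - D * beta_y
  p_eff <- lv_params(rx = rx_e, ry = ry_e,
                     Kx = p$Kx * rx_e / p$rx, Ky = p$Ky * ry_e / p$ry,
                     alpha_xy = p$alpha_xy, alpha_yx = p$alpha_yx)
  s0 <- c(0.4, 0.6)
  tA <- lv_simulate(s0, p, th, t_end = 300, n_out = 61)
  tB <- lv_simulate(s0, p_eff, t_end = 300, n_out = 61)
  expect_equal(tA$x, tB$x, tolerance = 1e-7)
  expect_equal(tA$y, tB$y, tolerance = 1e-7)
})

test_that("simulation input validation and trajectory export round-trip", {
  dp <- fx$regime2$dimensionless
  expect_error(lv_simulate(c(-0.1, 0.5), dp, t_end = 10), "non-negative")
  expect_error(lv_simulate(c(0.5, 0.5), dp, t_end = 0), "t_end")
  tr <- lv_simulate(c(0.5, 0.5), dp, t_end = 10, n_out = 11)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$u, tr$u, tolerance = 1e-12)
  expect_equal(attr(back, "meta")$coordinates, "dimensionless")
  unlink(c(path, paste0(path, ".json")))
})
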