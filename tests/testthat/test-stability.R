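test_that("equilibria carry the analytic eigenvalues and classes", {
  # P1 has eigenvalues (1, d) for any triple
  for (dp in random_triples(5, seed = 21)) {
    eq <- equilibria(dp)
    expect_equal(sort(Re(eq$P1$eigenvalues)), sort(c(1, dp$d)),
                 tolerance = 1e-9)
    expect_equal(eq$P1$stability_class, "unstable node")
  }
  # regime I fixture: P2 eigenvalues (1 - cd, -d), stable node
  dp1 <- fx$regime1$dimensionless
  eq1 <- equilibria(dp1)
  expect_equal(sort(Re(eq1$P2$eigenvalues)),
               sort(c(1 - dp1$c * dp1$d, -dp1$d)), tolerance = 1e-9)
  expect_equal(eq1$P2$stability_class, "stable node")
  # P3's second eigenvalue is d - f; its first is -1 (from the Jacobian)
  expect_equal(sort(Re(eq1$P3$eigenvalues)), sort(c(-1, dp1$d - dp1$f)),
               tolerance = 1e-9)
  # regime II fixture: P4 at the nullcline intersection
  eq2 <- equilibria(fx$regime2$dimensionless)
  expect_equal(eq2$P4$location, c(0.1 / 0.212, 0.112 / 0.212),
               tolerance = 1e-12)
  expect_equal(eq2$P4$stability_class, "stable node")
})

test_that("analytic Jacobian agrees with finite differences over random triples", {
  set.seed(22)
  for (i in 1:300) {
    dp <- dimensionless_params(runif(1, 0.3, 2), runif(1, 0.3, 1.6),
                               runif(1, 0.3, 1.6))
    for (e in equilibria(dp)) {
      ev_fd <- eigen(fd_jacobian(e$location[1], e$location[2], dp),
                     only.values = TRUE)$values
      # scale by the eigenvalue magnitude: P4 can sit far from the origin
      # near cf = 1, where finite differences lose absolute accuracy
      scale <- max(1, abs(Re(e$eigenvalues)))
      expect_lt(max(abs(sort(Re(e$eigenvalues)) - sort(Re(ev_fd)))) / scale,
                1e-6)
    }
  }
})

test_that("regime classification matches the published examples and is total", {
  expect_equal(classify_regime(dimensionless_params(1.65, 0.75, 0.45)), "I")
  expect_equal(classify_regime(dimensionless_params(1, 0.9, 0.788)), "II")
  expect_equal(classify_regime(dimensionless_params(1.65, 0.65, 0.69)), "III")
  expect_equal(classify_regime(dimensionless_params(1, 0.66, 0.7)), "IV")
  # boundary manifolds map to DEGENERATE
  expect_equal(classify_regime(dimensionless_params(2, 0.5, 0.4)),
               "DEGENERATE")  # cd = 1
  expect_equal(classify_regime(dimensionless_params(1.2, 0.7, 0.7)),
               "DEGENERATE")  # f = d
  # lv_params input is converted on the fly
  expect_equal(classify_regime(fx$regime4$kinetics), "IV")
})

test_that("long simulations terminate at each regime's predicted attractor", {
  suite <- generate_scenario_suite(seed = 5, n_per_regime = 5)
  set.seed(23)
  for (sc in suite) {
    dp <- sc$dimensionless
    eq <- equilibria(dp)
    s0 <- runif(2, 0.05, 1.2)
    fin <- as.numeric(tail(lv_simulate(s0, dp, t_end = 6000, n_out = 7), 1)[2:3])
    target <- switch(sc$regime,
      I = list(eq$P2$location),
      II = list(eq$P4$location),
      IV = list(eq$P3$location),
      III = list(eq$P2$location, eq$P3$location))
    dists <- vapply(target, function(z) sqrt(sum((fin - z)^2)), numeric(1))
    expect_lt(min(dists), 1e-4)
  }
})

test_that("crossing cd = 1 flips exactly one eigenvalue of P2", {
  d <- 0.8; f <- 0.5
  below <- equilibria(dimensionless_params(1 / d - 0.05, d, f))$P2
  above <- equilibria(dimensionless_params(1 / d + 0.05, d, f))$P2
  sb <- Re(below$eigenvalues); sa <- Re(above$eigenvalues)
  expect_equal(sum(sign(sort(sb)) != sign(sort(sa))), 1)
  expect_equal(below$stability_class, "saddle")
  expect_equal(above$stability_class, "stable node")
})

test_that("the separatrix splits the plane into the two basins", {
  dp <- dimensionless_params(1.65, 0.65, 0.69)
  sep <- separatrix(dp, t_max = 40, n = 300)
  P4 <- attr(sep, "P4")
  expect_equal(P4, c(-0.0725 / -0.1385, -0.04 / -0.1385), tolerance = 1e-12)
  # each branch starts at P4 and leaves monotonically in arc length
  b1 <- sep[sep$branch == 1, ]
  r <- sqrt((b1$u - P4[1])^2 + (b1$v - P4[2])^2)
  expect_lt(r[1], 1e-4)
  expect_gt(tail(r, 1), 0.2)
  # seeds offset on either side of the curve flow to different nodes
  eq <- equilibria(dp)
  mid <- as.numeric(b1[which.min(abs(r - 0.15)), c("u", "v")])
  nxt <- as.numeric(b1[which.min(abs(r - 0.16)), c("u", "v")])
  tang <- (nxt - mid) / sqrt(sum((nxt - mid)^2))
  nrm <- c(-tang[2], tang[1])
  ends <- lapply(list(mid + 0.02 * nrm, mid - 0.02 * nrm), function(s0)
    as.numeric(tail(lv_simulate(pmax(s0, 1e-9), dp, t_end = 6000,
                                n_out = 5), 1)[2:3]))
  d2P2 <- vapply(ends, function(z) sqrt(sum((z - eq$P2$location)^2)),
                 numeric(1))
  d2P3 <- vapply(ends, function(z) sqrt(sum((z - eq$P3$location)^2)),
                 numeric(1))
  hit <- ifelse(d2P2 < d2P3, "P2", "P3")
  expect_setequal(hit, c("P2", "P3"))
  # outside regime III the construction is refused
  expect_error(separatrix(fx$regime2$dimensionless), "regime III")
})

test_that("the Dulac certificate rules out closed orbits off the degenerate set", {
  d2 <- dulac_certificate(fx$regime2$dimensionless)
  expect_lt(d2$sign_coefficient, 0)
  expect_true(d2$conclusive)
  expect_equal(c(d2$m, d2$n), c(-2, -1), tolerance = 1e-12)
  d3 <- dulac_certificate(fx$regime3$dimensionless)
  expect_lt(d3$sign_coefficient, 0)
  d1 <- dulac_certificate(fx$regime1$dimensionless)
  expect_true(d1$conclusive)
  # the degenerate manifold cd - 1 = d - f
  c_ <- 1.5; d <- 0.9; f <- d - (c_ * d - 1)
  dg <- dulac_certificate(dimensionless_params(c_, d, f))
  expect_true(dg$degenerate_case)
  expect_false(dg$conclusive)
  expect_error(dulac_certificate(dimensionless_params(2, 0.9, 0.5)), "cf = 1")
})

test_that("unperturbed trajectories settle: stroboscopic displacement dies out", {
  fixtures <- list(fx$regime1$dimensionless, fx$regime2$dimensionless,
                   fx$regime3$dimensionless, fx$regime4$dimensionless)
  for (dp in fixtures) {
    tr <- lv_simulate(c(0.6, 0.35), dp, t_end = 800, n_out = 41)
    z <- as.matrix(tr[, 2:3])
    disp <- sqrt(rowSums((z[-1, , drop = FALSE] -
                          z[-nrow(z), , drop = FALSE])^2))
    expect_lt(tail(disp, 1), 1e-8)          # no residual periodic motion
    expect_lt(tail(disp, 1), disp[1] + 1e-15)
    # eventually monotone decay over the tail
    tail_disp <- tail(disp, 10)
    expect_true(all(diff(tail_disp) <= 1e-12))
  }
})
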