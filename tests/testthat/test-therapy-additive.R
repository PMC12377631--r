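test_that("the forcing amplitude follows the scaling identity", {
  p <- fx$regime4_forced$kinetics
  expect_equal(forcing_amplitude(0, -1 / 40, p), 0)
  expect_equal(forcing_amplitude(1, -1 / 40, p),
               (1 / 40) * 0.066 / (0.1^2 * 1), tolerance = 1e-12)
  expect_equal(forcing_amplitude(1, -1 / 40, p), 0.165, tolerance = 1e-12)
  expect_equal(forcing_amplitude(2, -1 / 40, p),
               2 * forcing_amplitude(1, -1 / 40, p))
  expect_error(forcing_amplitude(1, 0.025, p), "beta_y < 0")
})

test_that("forced equilibria reduce to the unforced set at A = 0", {
  dp <- dimensionless_params(1, 0.66, 1.1)
  q0 <- q_equilibria(dp, 0)
  eq <- equilibria(dp)
  expect_equal(q0$Q2$location, eq$P2$location, tolerance = 1e-12)
  # f > d: Q3 lands on P3, Q4 on the (non-physical here) P4
  expect_equal(q0$Q3$location, eq$P3$location, tolerance = 1e-12)
  expect_equal(q0$Q4$location, eq$P4$location, tolerance = 1e-12)
})

test_that("forced equilibria match the closed forms and stability claims", {
  dp <- dimensionless_params(1, 0.66, 1.1)
  q <- q_equilibria(dp, 0.1)
  expect_equal(attr(q, "Delta"), 0.44^2 - 4 * 0.1 * 0.1, tolerance = 1e-12)
  expect_true(q$Q3$exists && q$Q4$exists)
  # Q1's host coordinate is negative for any A > 0 and Q1 is unstable
  for (A in c(0.05, 0.2, 0.6)) {
    qq <- q_equilibria(dp, A)
    expect_lt(qq$Q1$location[2], 0)
    expect_true(qq$Q1$stability_class %in%
                c("unstable node", "unstable spiral", "saddle"))
    # Q1, Q2 v-coordinates are (d -/+ sqrt(d^2+4A))/2
    s <- sqrt(0.66^2 + 4 * A)
    expect_equal(qq$Q1$location[2], (0.66 - s) / 2, tolerance = 1e-12)
    expect_equal(qq$Q2$location[2], (0.66 + s) / 2, tolerance = 1e-12)
  }
  # Q2 gains stability precisely above A1
  amp <- bifurcation_amplitudes(dp)
  qlo <- q_equilibria(dp, amp$A1 - 1e-3)
  qhi <- q_equilibria(dp, amp$A1 + 1e-3)
  expect_false(qlo$Q2$stability_class == "stable node")
  expect_equal(qhi$Q2$stability_class, "stable node")
})

test_that("bifurcation amplitudes take their closed-form values", {
  dp <- dimensionless_params(1, 0.66, 1.1)
  amp <- bifurcation_amplitudes(dp)
  expect_equal(amp$A1, 0.34, tolerance = 1e-12)
  expect_equal(amp$A2, 0.44^2 / (4 * 0.1), tolerance = 1e-12)
  expect_equal(amp$A2, 0.484, tolerance = 1e-12)
  expect_lt(amp$A1, amp$A2)  # holds throughout regime IV with cf > 1
  # cd = 1 collapses A1 to zero; cf <= 1 leaves A2 undefined
  expect_equal(bifurcation_amplitudes(dimensionless_params(2, 0.5, 0.7))$A1, 0)
  expect_true(is.na(bifurcation_amplitudes(fx$regime2$dimensionless)$A2))
})

test_that("dose thresholds are dual to the bifurcation amplitudes", {
  # algebraic identity forcing_amplitude(Di) = Ai, checked over random sets
  set.seed(51)
  n_dual2 <- 0
  for (i in 1:200) {
    p <- lv_params(runif(1, 0.05, 0.2), runif(1, 0.03, 0.2),
                   runif(1, 0.5, 2), runif(1, 0.5, 2),
                   runif(1, 0.01, 0.3), runif(1, 0.01, 0.3))
    beta_y <- -runif(1, 0.005, 0.1)
    dp <- to_dimensionless(p)
    # near cf = 1 or f = d the identity is ill-conditioned (cancellation
    # is amplified differently along the two algebraic routes)
    if (abs(dp$c * dp$f - 1) < 1e-3 || abs(dp$f - dp$d) < 1e-3) next
    amp <- bifurcation_amplitudes(dp)
    dth <- tryCatch(dose_thresholds_additive(p, beta_y),
                    error = function(e) NULL)
    if (is.null(dth)) next  # cf = 1 boundary draw
    expect_equal(forcing_amplitude(abs(dth$D1), beta_y, p) *
                   sign(dth$D1), amp$A1, tolerance = 1e-12)
    if (!is.na(dth$D2)) {
      expect_equal(forcing_amplitude(dth$D2, beta_y, p), amp$A2,
                   tolerance = 1e-12)
      n_dual2 <- n_dual2 + 1
    }
  }
  expect_gt(n_dual2, 20)
  # vanishing-numerator boundaries
  p_cd1 <- lv_params(0.1, 0.075, 1, 1, alpha_xy = 0.1, alpha_yx = 0.2)
  expect_equal(dose_thresholds_additive(p_cd1, -0.02)$D1, 0)
  p_fd <- lv_params(0.1, 0.066, 1, 1, alpha_xy = 0.2, alpha_yx = 0.066)
  expect_equal(dose_thresholds_additive(p_fd, -0.02)$D2, 0)
})

test_that("the saddle-node collision happens at A2 with a zero eigenvalue", {
  dp <- dimensionless_params(1, 0.66, 1.1)
  A2 <- bifurcation_amplitudes(dp)$A2
  # the interior pair approaches as A increases toward A2
  gaps <- vapply(c(0.3, 0.4, 0.45, 0.48), function(A) {
    q <- q_equilibria(dp, A)
    sqrt(sum((q$Q3$location - q$Q4$location)^2))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  # at A2 the collided point exists with an eigenvalue at zero
  qc <- q_equilibria(dp, A2)
  expect_equal(qc$Q3$location, qc$Q4$location, tolerance = 1e-9)
  expect_lt(min(abs(Re(qc$Q3$eigenvalues))), 1e-6)
  # beyond A2 the pair is gone
  qg <- q_equilibria(dp, A2 + 0.01)
  expect_false(qg$Q3$exists)
})

test_that("the additive planner follows the decision rules and simulation", {
  dp <- dimensionless_params(1, 0.66, 1.1)  # regime IV, cf > 1
  expect_equal(plan_outcome_additive(dp, A = 0)$outcome, "IV")
  expect_equal(plan_outcome_additive(dp, A = 0.5)$outcome, "I*")
  expect_equal(plan_outcome_additive(dp, A = 0.2)$outcome, "II*")
  # A1 < A < A2 here with c(f-d) = 0.44 > 2(cf-1) = 0.2: still tumor-free
  expect_equal(plan_outcome_additive(dp, A = 0.4)$outcome, "I*")
  # interior-pair branch: c(f-d) < 2(cf-1) keeps a stable coexistence point
  dp3 <- dimensionless_params(1.5, 0.6, 1.3 / 1.5)
  expect_equal(classify_regime(dp3), "IV")
  amp3 <- bifurcation_amplitudes(dp3)
  expect_lt(dp3$c * (dp3$f - dp3$d), 2 * (dp3$c * dp3$f - 1))
  A_mid <- (amp3$A1 + amp3$A2) / 2
  expect_equal(plan_outcome_additive(dp3, A = A_mid)$outcome, "III*")
  # regime IV with cf < 1 and regimes II, III
  dp4 <- fx$regime4$dimensionless
  A1_4 <- bifurcation_amplitudes(dp4)$A1
  expect_equal(plan_outcome_additive(dp4, A = A1_4 * 1.2)$outcome, "I*")
  expect_equal(plan_outcome_additive(dp4, A = A1_4 * 0.5)$outcome, "II*")
  dp2 <- fx$regime2$dimensionless
  A1_2 <- bifurcation_amplitudes(dp2)$A1
  expect_equal(plan_outcome_additive(dp2, A = A1_2 * 2)$outcome, "I*")
  expect_equal(plan_outcome_additive(dp2, A = A1_2 * 0.5)$outcome, "II*")
  dpIII <- fx$regime3$dimensionless
  A2_3 <- bifurcation_amplitudes(dpIII)$A2
  expect_equal(plan_outcome_additive(dpIII, A = A2_3 * 1.5)$outcome, "I*")
  expect_equal(plan_outcome_additive(dpIII, A = A2_3 * 0.5)$outcome, "III*")

  # each predicted outcome agrees with the simulated attractor structure
  check_sim <- function(dp, A, outcome) {
    fr <- dimensionless_forcing(A)
    fin <- as.numeric(tail(lv_simulate(c(0.5, 0.5), dp, fr, t_end = 4000,
                                       n_out = 9), 1)[2:3])
    if (outcome == "I*") expect_lt(fin[1], 1e-5) else expect_gt(fin[1], 1e-3)
    expect_gt(fin[2], 1e-3)  # the host never vanishes under host boosting
  }
  check_sim(dp, 0.5, "I*")
  check_sim(dp, 0.2, "II*")
  check_sim(dp3, A_mid, "III*")
  check_sim(dp4, A1_4 * 0.5, "II*")
})

test_that("the host stays bounded away from zero under additive forcing", {
  set.seed(52)
  for (i in 1:25) {
    dp <- dimensionless_params(runif(1, 0.5, 1.8), runif(1, 0.4, 1.4),
                               runif(1, 0.4, 1.4))
    A <- runif(1, 0.02, 0.5)
    tr <- lv_simulate(runif(2, 0.05, 1), dp, dimensionless_forcing(A),
                      t_end = 500, n_out = 101)
    expect_gt(min(tr$v[tr$tau > 100]), 0.01)
  }
})

test_that("original-coordinate planner input reproduces the dose thresholds", {
  p <- fx$regime4_forced$kinetics
  pl <- plan_outcome_additive(p, beta_y = -1 / 40, D = 1)
  expect_equal(pl$A, 0.165, tolerance = 1e-12)
  expect_equal(pl$A1, 0.34, tolerance = 1e-12)
  expect_equal(pl$A2, 0.484, tolerance = 1e-12)
  expect_equal(pl$outcome, "II*")  # A = 0.165 < A1
  expect_equal(forcing_amplitude(pl$doses$D2, -1 / 40, p), pl$A2,
               tolerance = 1e-12)
})
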