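test_that("effective parameters rescale d only, per direct substitution", {
  p <- fx$regime4$kinetics
  dp0 <- to_dimensionless(p)
  # D = 0 reproduces the baseline triple
  e0 <- effective_params(p, 0, 0.05, 0.01)
  expect_equal(unlist(e0), unlist(dp0), tolerance = 1e-12)
  # direct substitution example
  e <- effective_params(p, 0.5, 0.05, 0.01)
  expect_equal(e$c, dp0$c)
  expect_equal(e$f, dp0$f)
  expect_equal(e$d, (0.066 - 0.005) / (0.1 - 0.025), tolerance = 1e-12)
  # beta_x/beta_y = rx/ry leaves d* constant in D
  bx <- 0.05; by <- bx * p$ry / p$rx
  for (D in c(0.2, 0.6, 1))
    expect_equal(effective_params(p, D, bx, by)$d, dp0$d, tolerance = 1e-12)
  # beyond an extinction dose the planner signal is returned, not an error
  e_ext <- effective_params(p, 3, 0.05, 0.01)
  expect_s3_class(e_ext, "lv_extinction")
  expect_equal(e_ext$which, "tumor")
})

test_that("dose thresholds match the closed forms for the regime IV fixture", {
  p <- fx$regime4$kinetics
  thr <- dose_thresholds(p, 0.05, 0.01)
  expect_equal(thr$D1, 0.066 * 0.034 / (0.0033 - 0.00066), tolerance = 1e-12)
  expect_equal(thr$D1, 0.85, tolerance = 1e-12)
  expect_equal(thr$D2, 0.1 * 0.004 / (0.0035 - 0.001), tolerance = 1e-12)
  expect_equal(thr$D2, 0.16, tolerance = 1e-12)
  # boundary degeneracies: vanishing numerators
  p_cd1 <- lv_params(0.1, 0.075, 1, 1, alpha_xy = 0.1, alpha_yx = 0.05)
  expect_equal(dose_thresholds(p_cd1, 0.05, 0.01)$D1, 0)
  p_fd <- lv_params(0.1, 0.066, 1, 1, alpha_xy = 0.05, alpha_yx = 0.066)
  expect_equal(dose_thresholds(p_fd, 0.05, 0.01)$D2, 0)
  # ineffective therapy is refused
  expect_error(dose_thresholds(p, 0.01, 0.05), "ineffective")
})

test_that("d*(D) is strictly increasing exactly when therapy is effective", {
  p <- fx$regime4$kinetics
  Ds <- seq(0, 1, by = 0.1)
  dstar <- vapply(Ds, function(D) effective_params(p, D, 0.05, 0.01)$d,
                  numeric(1))
  expect_true(all(diff(dstar) > 0))
  # reversed coefficients: decreasing
  dstar2 <- vapply(Ds, function(D) effective_params(p, D, 0.01, 0.05)$d,
                   numeric(1))
  expect_true(all(diff(dstar2) < 0))
})

test_that("classification switches exactly at the thresholds", {
  p <- fx$regime4$kinetics
  thr <- dose_thresholds(p, 0.05, 0.01)
  eps <- 1e-6
  cd_at <- function(D) {
    e <- effective_params(p, D, 0.05, 0.01)
    e$c * e$d
  }
  expect_lt(cd_at(thr$D1 - eps), 1)
  expect_gt(cd_at(thr$D1 + eps), 1)
  df_at <- function(D) {
    e <- effective_params(p, D, 0.05, 0.01)
    e$d - e$f
  }
  expect_lt(df_at(thr$D2 - eps), 0)
  expect_gt(df_at(thr$D2 + eps), 0)
})

test_that("the outcome planner follows the per-regime decision rules", {
  p <- fx$regime4$kinetics  # cf = 0.7 < 1; D1 = 0.85, D2 = 0.16
  expect_equal(plan_outcome(p, 0.05, 0.01, 0)$outcome, "IV")
  expect_equal(plan_outcome(p, 0.05, 0.01, 0.1)$outcome, "IV")
  expect_equal(plan_outcome(p, 0.05, 0.01, 0.5)$outcome, "II")
  expect_equal(plan_outcome(p, 0.05, 0.01, 1)$outcome, "I")
  expect_equal(plan_outcome(p, 0.05, 0.01, 0.16)$outcome, "DEGENERATE")
  expect_equal(plan_outcome(p, 0.05, 0.01, 10)$outcome, "both_extinct")
  # intervals partition [0, Inf)
  tab <- plan_outcome(p, 0.05, 0.01, 0.5)$dose_intervals
  expect_equal(tab$lower[1], 0)
  expect_equal(tail(tab$upper, 1), Inf)
  expect_equal(tab$lower[-1], head(tab$upper, -1))
  # baselines II and III use the single relevant threshold
  suite <- generate_scenario_suite(seed = 9, n_per_regime = 1)
  for (sc in suite) {
    bx <- sc$therapy$effective["beta_x"]; by <- sc$therapy$effective["beta_y"]
    if (sc$regime == "II") {
      thr <- dose_thresholds(sc$params, bx, by)
      expect_equal(plan_outcome(sc$params, bx, by, thr$D1 * 1.5)$outcome, "I")
      expect_equal(plan_outcome(sc$params, bx, by, thr$D1 * 0.5)$outcome, "II")
    }
    if (sc$regime == "III") {
      thr <- dose_thresholds(sc$params, bx, by)
      expect_equal(plan_outcome(sc$params, bx, by, thr$D2 * 1.5)$outcome, "I")
      expect_equal(plan_outcome(sc$params, bx, by, thr$D2 * 0.5)$outcome, "III")
    }
  }
})

test_that("planned outcomes agree with simulation of the perturbed system", {
  suite <- generate_scenario_suite(seed = 17, n_per_regime = 3)
  set.seed(41)
  n_checked <- 0
  for (sc in suite) {
    if (sc$regime == "I") next
    bx <- unname(sc$therapy$effective["beta_x"])
    by <- unname(sc$therapy$effective["beta_y"])
    thr <- dose_thresholds(sc$params, bx, by)
    D <- min(max(thr$D1, thr$D2) * 1.5,
             0.9 * min(sc$params$rx / bx,
                       if (by > 0) sc$params$ry / by else Inf))
    pl <- plan_outcome(sc$params, bx, by, D)
    if (pl$outcome != "I") next
    th <- therapy_spec("proportional_constant", D = D, beta_x = bx,
                       beta_y = by)
    fin <- as.numeric(tail(lv_simulate(c(0.5, 0.5), sc$params, th,
                                       t_end = 4000 / sc$params$rx,
                                       n_out = 9), 1)[2:3])
    expect_lt(fin[1], 1e-5)  # tumor eliminated in the predicted regime I
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 6)
  # simulate option reports practical elimination
  p <- fx$regime4$kinetics
  pl <- plan_outcome(p, 0.05, 0.01, 1, simulate = TRUE,
                     t_end = 4000 / p$rx)
  expect_true(pl$tumor_eliminated)
})
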