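#' Named reference parameter sets
#'
#' The canonical kinetic and dimensionless parameter sets used throughout
#' the package's examples and tests: one representative per dynamical
#' regime, the periodically forced tumor-dominance scenario, the parameter
#' point where the maximum Lyapunov exponent of the forced system attains
#' a (negative) local maximum, and the LV parameter octet obtained by
#' fitting unperturbed Ehrlich tumor volumes.
#'
#' All regime sets share `Kx = Ky = 1` cell and `rx = 0.1`/day. The
#' `regime3` entry carries the dimensionless triple directly because the
#' originally published kinetic set for that regime is internally
#' inconsistent (it implies `c` of about 0.38 rather than the stated 1.65,
#' and `cd < 1` where regime III needs `cd > 1`); the accompanying
#' `kinetics_printed` field preserves the inconsistent set with a flag.
#'
#' @return A named list of fixtures. Each regime entry holds `kinetics`
#'   (an [lv_params]), the induced `dimensionless` triple and the `regime`
#'   label; `regime4_forced` adds the periodic [therapy_spec];
#'   `lce_local_max` is the named `(c, d, f, A, omega)` vector;
#'   `ehrlich_fit` holds the fitted `kinetics`, `x0` and `y0`.
#' @examples
#' fx <- lv_fixtures()
#' classify_regime(fx$regime2$dimensionless)
#' @export
lv_fixtures <- function() {
  k1 <- lv_params(rx = 0.1, ry = 0.075, Kx = 1, Ky = 1,
                  alpha_xy = 0.1237, alpha_yx = 0.045)
  k2 <- lv_params(rx = 0.1, ry = 0.09, Kx = 1, Ky = 1,
                  alpha_xy = 0.09, alpha_yx = 0.0788)
  k3 <- lv_params(rx = 0.1, ry = 0.065, Kx = 1, Ky = 1,
                  alpha_xy = 0.0247, alpha_yx = 0.069)
  k4 <- lv_params(rx = 0.1, ry = 0.066, Kx = 1, Ky = 1,
                  alpha_xy = 0.066, alpha_yx = 0.07)
  k4f <- lv_params(rx = 0.1, ry = 0.066, Kx = 1, Ky = 1,
                   alpha_xy = 0.066, alpha_yx = 0.11)
  list(
    regime1 = list(kinetics = k1, dimensionless = to_dimensionless(k1),
                   regime = "I"),
    regime2 = list(kinetics = k2, dimensionless = to_dimensionless(k2),
                   regime = "II"),
    regime3 = list(dimensionless = dimensionless_params(1.65, 0.65, 0.69),
                   regime = "III",
                   kinetics_printed = k3, inconsistent = TRUE,
                   note = paste("published kinetic set implies c ~ 0.38,",
                                "not 1.65; the dimensionless triple is",
                                "authoritative")),
    regime4 = list(kinetics = k4, dimensionless = to_dimensionless(k4),
                   regime = "IV"),
    regime4_forced = list(kinetics = k4f,
                          dimensionless = to_dimensionless(k4f),
                          regime = "IV",
                          therapy = therapy_spec("periodic_additive",
                                                 D = 1, beta_x = 0,
                                                 beta_y = -1 / 40,
                                                 omega = 1 / 14)),
    lce_local_max = c(c = 0.933816, d = 0.999086, f = 1.27836,
                      A = 0.100613, omega = 0.496117),
    ehrlich_fit = list(kinetics = lv_params(rx = 4.83671566,
                                            ry = 6.36103209,
                                            Kx = 3.21508273,
                                            Ky = 2.78479322,
                                            alpha_xy = 1.52999021,
                                            alpha_yx = 1.97864993),
                       x0 = 0.46733650, y0 = 2.38718513))
}

#' Synthetic tumor-volume series specification
#'
#' Describes how to generate a synthetic growth curve: kinetic parameters
#' and initial state of the generating model, sampling times, and a
#' multiplicative log-normal noise level. The defaults emulate
#' unperturbed Ehrlich tumor volume measurements in mice: a
#' logistic-like rise from about 0.5 cm\eqn{^3} toward a 2-3 cm\eqn{^3}
#' plateau, sampled at 12 equally spaced points over 30 days with 5%
#' multiplicative measurement noise (volume errors scale with size).
#'
#' @param params generating [lv_params]; defaults to the Ehrlich-fit
#'   fixture.
#' @param state0 initial `(x0, y0)` at `t = 0`.
#' @param times sampling times, days.
#' @param sigma log-normal noise scale (`0` for the exact model curve).
#' @param seed integer seed or `NULL`.
#' @return An object of class `lv_synth_spec`.
#' @export
synthetic_spec <- function(params = NULL, state0 = NULL,
                           times = seq(0, 30, length.out = 12),
                           sigma = 0.05, seed = NULL) {
  if (is.null(params)) {
    fx <- lv_fixtures()$ehrlich_fit
    params <- fx$kinetics
    if (is.null(state0)) state0 <- c(fx$x0, fx$y0)
  }
  stopifnot(inherits(params, "lv_params"))
  if (is.null(state0)) state0 <- c(0.5, 1)
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(diff(times) <= 0) || any(times < 0))
    stop("times must be non-negative and strictly increasing")
  structure(list(params = params, state0 = state0, times = times,
                 sigma = sigma, seed = seed),
            class = "lv_synth_spec")
}

#' Generate a synthetic tumor-volume series
#'
#' Simulates the tumor component from the generating parameters, samples
#' it at the specified times and applies multiplicative log-normal noise
#' `V_i = x(t_i) * exp(sigma * Z_i)`. With `sigma = 0` the exact model
#' curve is returned; with a fixed seed the output is reproducible.
#'
#' @param spec an [synthetic_spec()] object.
#' @return An [volume_series] with the generating spec in attribute
#'   `"spec"`.
#' @export
generate_volume_series <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "lv_synth_spec"))
  tr <- lv_simulate(spec$state0, spec$params, t_end = max(spec$times),
                    times = sort(unique(c(0, spec$times))))
  x <- tr$x[match(spec$times, tr$t)]
  if (spec$sigma > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    x <- x * exp(spec$sigma * stats::rnorm(length(x)))
  }
  out <- volume_series(spec$times, x)
  attr(out, "spec") <- spec
  out
}

#' Generate a suite of random regime scenarios
#'
#' Rejection-samples kinetic parameter sets for each of the four regimes
#' (covering both `cf` sub-cases of regime IV) and bundles each with
#' therapy coefficient draws for planner tests: an effective proportional
#' pair (`ry*beta_x - rx*beta_y > 0`), an ineffective pair, and a
#' host-directed additive coefficient (`beta_y < 0`).
#'
#' @param seed integer seed.
#' @param n_per_regime scenarios per regime class (`>= 1`).
#' @param Kx,Ky carrying capacities of the generated sets.
#' @return A list of scenarios; each has `params`, `regime` (the label its
#'   parameters classify to), `subcase` (`"cf<1"`/`"cf>1"`), and a
#'   `therapy` list with `effective`, `ineffective` and
#'   `additive_beta_y`.
#' @export
generate_scenario_suite <- function(seed = 1L, n_per_regime = 3L,
                                    Kx = 1, Ky = 1) {
  stopifnot(n_per_regime >= 1)
  set.seed(seed)
  targets <- c(rep("I", n_per_regime), rep("II", n_per_regime),
               rep("III", n_per_regime),
               rep("IV_lo", n_per_regime), rep("IV_hi", n_per_regime))
  draw_one <- function(target) {
    repeat {
      rx <- stats::runif(1, 0.05, 0.15)
      ry <- rx * stats::runif(1, 0.4, 1.6)
      alpha_xy <- stats::runif(1, 0.2, 3) * rx / Kx
      alpha_yx <- stats::runif(1, 0.2, 3) * ry / Ky
      p <- lv_params(rx, ry, Kx, Ky, alpha_xy, alpha_yx)
      dp <- to_dimensionless(p)
      reg <- classify_regime(dp)
      lab <- if (reg == "IV") {
        if (dp$c * dp$f > 1) "IV_hi" else "IV_lo"
      } else reg
      if (lab == target) return(list(params = p, dimensionless = dp,
                                     regime = reg,
                                     subcase = if (dp$c * dp$f > 1)
                                       "cf>1" else "cf<1"))
    }
  }
  out <- lapply(targets, function(tg) {
    sc <- draw_one(tg)
    beta_x <- stats::runif(1, 0.02, 0.1)
    ratio <- sc$params$ry * beta_x / sc$params$rx
    sc$therapy <- list(
      effective = c(beta_x = beta_x,
                    beta_y = stats::runif(1, 0, 0.8) * ratio),
      ineffective = c(beta_x = beta_x,
                      beta_y = stats::runif(1, 1.2, 2) * ratio),
      additive_beta_y = -stats::runif(1, 0.01, 0.05))
    sc
  })
  out
}
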