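#' Effective dimensionless parameters under proportional continuous therapy
#'
#' A continuous dose `D` with proportional effect rescales the growth rates
#' to `rx - D*beta_x` and `ry - D*beta_y`, leaving the system a competitive
#' LV model with unchanged `c` and `f` and
#' \deqn{d^*(D) = (r_y - D\beta_y)/(r_x - D\beta_x).}
#' The therapy therefore moves the regime only through `d*`, and is
#' effective (i.e. `d*` increases with dose) iff
#' `ry*beta_x - rx*beta_y > 0`.
#'
#' @param params an [lv_params] object.
#' @param D relative dose.
#' @param beta_x,beta_y per-day effect coefficients on tumor and host.
#' @return An [dimensionless_params] object `(c, d*, f)`; if the dose
#'   reaches an extinction threshold (`rx - D*beta_x <= 0` or
#'   `ry - D*beta_y <= 0`) an object of class `lv_extinction` is returned
#'   instead, naming which population(s) the dose drives to zero.
#' @export
effective_params <- function(params, D, beta_x, beta_y) {
  stopifnot(inherits(params, "lv_params"), D >= 0)
  rx_e <- params$rx - D * beta_x
  ry_e <- params$ry - D * beta_y
  if (rx_e <= 0 || ry_e <= 0) {
    which <- c("tumor", "host")[c(rx_e <= 0, ry_e <= 0)]
    return(structure(list(which = which, D = D), class = "lv_extinction"))
  }
  dimensionless_params(c = params$Ky * params$alpha_xy / params$ry,
                       d = ry_e / rx_e,
                       f = params$Kx * params$alpha_yx / params$rx)
}

#' @export
print.lv_extinction <- function(x, ...) {
  cat(sprintf("Dose D = %g drives the %s population(s) to extinction\n",
              x$D, paste(x$which, collapse = " and ")))
  invisible(x)
}

#' Dose thresholds for proportional continuous therapy
#'
#' The regime conditions `c d* > 1` and `d* > f` switch at the doses
#' \deqn{D_1 = \frac{r_y (r_x - K_y\alpha_{xy})}{r_y\beta_x - \beta_y K_y \alpha_{xy}}, \qquad
#'       D_2 = \frac{r_x (K_x\alpha_{yx} - r_y)}{\beta_x K_x \alpha_{yx} - r_x\beta_y}.}
#' When a threshold's numerator is negative the corresponding condition
#' already holds at `D = 0`; it is then reported as 0 with a flag instead
#' of a negative dose.
#'
#' @inheritParams effective_params
#' @return An object of class `lv_prop_thresholds`: list with `D1`, `D2`
#'   (clamped to 0), `D1_raw`, `D2_raw`, and flags
#'   `D1_always`/`D2_always` marking conditions satisfied for every dose.
#' @export
dose_thresholds <- function(params, beta_x, beta_y) {
  stopifnot(inherits(params, "lv_params"))
  if (params$ry * beta_x - params$rx * beta_y <= 0)
    stop("ineffective therapy: requires ry*beta_x - rx*beta_y > 0 ",
         "(d* must increase with dose)")
  with(params, {
    D1_raw <- ry * (rx - Ky * alpha_xy) / (ry * beta_x - beta_y * Ky * alpha_xy)
    D2_raw <- rx * (Kx * alpha_yx - ry) / (beta_x * Kx * alpha_yx - rx * beta_y)
    structure(list(D1 = max(D1_raw, 0), D2 = max(D2_raw, 0),
                   D1_raw = D1_raw, D2_raw = D2_raw,
                   D1_always = D1_raw < 0, D2_always = D2_raw < 0),
              class = "lv_prop_thresholds")
  })
}

#' @export
print.lv_prop_thresholds <- function(x, ...) {
  cat(sprintf("Proportional-therapy dose thresholds: D1 = %g%s, D2 = %g%s\n",
              x$D1, if (x$D1_always) " (cd* > 1 for every dose)" else "",
              x$D2, if (x$D2_always) " (d* > f for every dose)" else ""))
  invisible(x)
}

#' Outcome planner for proportional continuous therapy
#'
#' Predicts the regime reached under a continuous proportional-effect dose
#' `D`, following the per-regime decision rules: from regime IV,
#' `D > max(D1, D2)` reaches regime I, `cf < 1` with `D1 > D > D2` reaches
#' II, `cf > 1` with `D2 > D > D1` reaches III, and `D < min(D1, D2)`
#' stays in IV; from III, `D > D2` reaches I; from II, `D > D1` reaches I.
#' Doses beyond `rx/beta_x` (resp. `ry/beta_y`) extinguish the tumor
#' (resp. host) outright. Doses exactly at a threshold are labelled
#' `"DEGENERATE"`. The plan also records the relapse caveat: when therapy
#' is withdrawn before the tumor is practically eliminated, the system
#' returns to its baseline regime.
#'
#' @inheritParams effective_params
#' @param simulate logical; when `TRUE`, additionally integrate the
#'   perturbed system and report whether the tumor falls below
#'   `floor`.
#' @param state0,t_end initial state and horizon for the optional
#'   simulation.
#' @param floor practical elimination cutoff for the tumor population
#'   (default `1e-6 * Kx`).
#' @param tol boundary tolerance for threshold comparisons.
#' @return An object of class `lv_prop_plan`: list with the baseline
#'   regime, effectiveness flag, thresholds, extinction doses, the
#'   predicted `outcome` for `D`, a dose-interval table partitioning
#'   `[0, Inf)`, the relapse flag and (optionally) simulation results.
#' @examples
#' p <- lv_params(0.1, 0.066, 1, 1, 0.066, 0.07)  # regime IV
#' plan_outcome(p, beta_x = 0.05, beta_y = 0.01, D = 0.5)
#' @export
plan_outcome <- function(params, beta_x, beta_y, D,
                         simulate = FALSE, state0 = c(0.5, 0.5),
                         t_end = NULL, floor = 1e-6 * params$Kx,
                         tol = 1e-12) {
  stopifnot(inherits(params, "lv_params"), D >= 0)
  baseline <- classify_regime(params)
  effective <- params$ry * beta_x - params$rx * beta_y > 0
  ext_x <- if (beta_x > 0) params$rx / beta_x else Inf
  ext_y <- if (beta_y > 0) params$ry / beta_y else Inf

  if (baseline == "I") {
    thr <- NULL
    outcome_fun <- function(D) {
      if (D >= min(ext_x, ext_y) - tol) {
        if (D >= max(ext_x, ext_y) - tol) "both_extinct"
        else if (ext_x <= ext_y) "tumor_extinct" else "host_extinct"
      } else "I"
    }
  } else {
    thr <- dose_thresholds(params, beta_x, beta_y)
    cf <- params$Kx * params$Ky * params$alpha_xy * params$alpha_yx /
      (params$rx * params$ry)
    D1 <- thr$D1; D2 <- thr$D2
    regime_map <- function(D) {
      switch(baseline,
        IV = if (D > max(D1, D2)) "I"
             else if (cf < 1 && D < D1 && D > D2) "II"
             else if (cf > 1 && D < D2 && D > D1) "III"
             else if (D < min(D1, D2)) "IV"
             else "DEGENERATE",
        III = if (D > D2) "I" else "III",
        II = if (D > D1) "I" else "II",
        "DEGENERATE")
    }
    outcome_fun <- function(D) {
      if (D >= min(ext_x, ext_y) - tol) {
        if (D >= max(ext_x, ext_y) - tol) return("both_extinct")
        return(if (ext_x <= ext_y) "tumor_extinct" else "host_extinct")
      }
      breaks <- c(D1, D2)
      if (any(abs(D - breaks) <= tol * max(1, D))) return("DEGENERATE")
      regime_map(D)
    }
  }

  # dose-interval table partitioning [0, Inf)
  brk <- sort(unique(c(0, if (!is.null(thr)) c(thr$D1, thr$D2),
                       ext_x[is.finite(ext_x)], ext_y[is.finite(ext_y)],
                       Inf)))
  mids <- (utils::head(brk, -1L) + utils::tail(brk, -1L)) / 2
  mids[!is.finite(mids)] <- utils::head(brk, -1L)[!is.finite(mids)] * 2 + 1
  table <- data.frame(lower = utils::head(brk, -1L),
                      upper = utils::tail(brk, -1L),
                      outcome = vapply(mids, outcome_fun, character(1L)))

  sim <- NULL
  tumor_eliminated <- NA
  if (simulate) {
    th <- therapy_spec("proportional_constant", D = D,
                       beta_x = beta_x, beta_y = beta_y)
    if (is.null(t_end)) t_end <- 2000 / params$rx
    sim <- lv_simulate(state0, params, th, t_end = t_end, n_out = 200L)
    tumor_eliminated <- utils::tail(sim$x, 1L) < floor
  }

  structure(list(baseline = baseline, effectiveness = effective,
                 thresholds = thr,
                 extinction_doses = c(tumor = ext_x, host = ext_y),
                 D = D, outcome = outcome_fun(D),
                 dose_intervals = table,
                 relapse_on_withdrawal = TRUE,
                 tumor_eliminated = tumor_eliminated,
                 simulation = sim),
            class = "lv_prop_plan")
}

#' @export
print.lv_prop_plan <- function(x, ...) {
  cat(sprintf("Proportional-therapy plan (baseline regime %s, therapy %s)\n",
              x$baseline,
              if (x$effectiveness) "effective" else "ineffective"))
  if (!is.null(x$thresholds))
    cat(sprintf("  D1 = %g, D2 = %g; extinction doses: tumor %g, host %g\n",
                x$thresholds$D1, x$thresholds$D2,
                x$extinction_doses[1L], x$extinction_doses[2L]))
  cat(sprintf("  dose D = %g -> %s\n", x$D, x$outcome))
  cat("  dose intervals:\n")
  print(x$dose_intervals, row.names = FALSE)
  cat("  note: withdrawal before practical elimination returns the system",
      "to its baseline regime\n")
  invisible(x)
}
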