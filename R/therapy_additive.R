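#' Dimensionless forcing amplitude of host-directed constant therapy
#'
#' A constant dose destroying `D*beta_y` host cells per day with
#' `beta_y < 0` (i.e. boosting the host) enters the dimensionless host
#' equation as the constant forcing
#' \deqn{A = -D\,\beta_y\, r_y /(r_x^2 K_y) \ge 0.}
#'
#' @param D relative dose, `>= 0`.
#' @param beta_y host effect coefficient, must be negative
#'   (host-directed boost).
#' @param params an [lv_params] object.
#' @return The non-negative amplitude `A`.
#' @export
forcing_amplitude <- function(D, beta_y, params) {
  stopifnot(inherits(params, "lv_params"), D >= 0)
  if (beta_y >= 0)
    stop("host-directed additive therapy requires beta_y < 0")
  -D * beta_y * params$ry / (params$rx^2 * params$Ky)
}

#' Equilibria of the additively forced dimensionless system
#'
#' With constant forcing `A` in the host equation the fixed points are
#' `Q1 = (0, (d - sqrt(d^2+4A))/2)`, `Q2 = (0, (d + sqrt(d^2+4A))/2)` and,
#' when the discriminant \eqn{\Delta = (f-d)^2 - 4A(cf-1)} is non-negative,
#' the interior pair `Q3`, `Q4` with `v = (f - d -/+ sqrt(Delta))/(2(cf-1))`
#' and `u = 1 - c v`. `Q1` (negative host coordinate) is always unstable;
#' `Q2` becomes stable for `A` above the bifurcation amplitude `A1`.
#' Eigenvalues come from the Jacobian of the forced field (identical to the
#' unforced Jacobian since the forcing is additive). Non-physical
#' equilibria are reported with `physical = FALSE` rather than dropped. At
#' `Delta = 0` the collided point `Q3 = Q4` is tagged as a saddle-node.
#'
#' @param dp an [dimensionless_params] object.
#' @param A non-negative forcing amplitude.
#' @param tol degeneracy tolerance.
#' @return An object of class `lv_equilibria` with labels `Q1`..`Q4` and
#'   attribute `Delta`; when `Delta < 0`, `Q3`/`Q4` are reported with
#'   `location = NA` and `exists = FALSE`.
#' @export
q_equilibria <- function(dp, A, tol = 1e-9) {
  stopifnot(inherits(dp, "lv_dimparams"), A >= 0)
  c_ <- dp$c; d <- dp$d; f <- dp$f
  s <- sqrt(d^2 + 4 * A)
  Delta <- (f - d)^2 - 4 * A * (c_ * f - 1)
  out <- list(Q1 = .equilibrium_report("Q1", c(0, (d - s) / 2), dp, tol),
              Q2 = .equilibrium_report("Q2", c(0, (d + s) / 2), dp, tol))
  out$Q1$exists <- out$Q2$exists <- TRUE
  if (abs(c_ * f - 1) <= tol) {
    # interior equation degenerates to linear: single root when f != d
    if (abs(f - d) > tol) {
      v <- A / (f - d)  # the quadratic term vanishes: (d - f) v + A = 0
      q <- .equilibrium_report("Q3", c(1 - c_ * v, v), dp, tol)
      q$exists <- TRUE
      out$Q3 <- q
      out$Q4 <- list(label = "Q4", location = c(NA_real_, NA_real_),
                     eigenvalues = complex(0), stability_class = "absent",
                     physical = FALSE, exists = FALSE)
    }
  } else if (Delta >= -tol) {
    Ds <- sqrt(max(Delta, 0))
    v3 <- (f - d - Ds) / (2 * (c_ * f - 1))
    v4 <- (f - d + Ds) / (2 * (c_ * f - 1))
    q3 <- .equilibrium_report("Q3", c(1 - c_ * v3, v3), dp, tol)
    q4 <- .equilibrium_report("Q4", c(1 - c_ * v4, v4), dp, tol)
    q3$exists <- q4$exists <- TRUE
    if (Delta <= tol) {
      q3$stability_class <- q4$stability_class <- "saddle-node (collided)"
    }
    out$Q3 <- q3; out$Q4 <- q4
  } else {
    absent <- function(lab) list(label = lab,
                                 location = c(NA_real_, NA_real_),
                                 eigenvalues = complex(0),
                                 stability_class = "absent (Delta < 0)",
                                 physical = FALSE, exists = FALSE)
    out$Q3 <- absent("Q3"); out$Q4 <- absent("Q4")
  }
  structure(out, class = "lv_equilibria", dimparams = dp, A = A,
            Delta = Delta)
}

#' Bifurcation amplitudes of the additively forced system
#'
#' `A1 = (1 - cd)/c^2` is the amplitude at which `Q2` (tumor-free state)
#' gains stability, one interior branch crossing the `u = 0` axis through
#' it; `A2 = (f - d)^2 / (4(cf - 1))` is the saddle-node amplitude at
#' which `Q3` and `Q4` collide (`Delta = 0`). `A2` is only meaningful for
#' `cf > 1`: for `cf <= 1` the discriminant is positive for every `A >= 0`
#' and `NA` is returned.
#'
#' @param dp an [dimensionless_params] object.
#' @return List with `A1` and `A2` (possibly `NA`).
#' @export
bifurcation_amplitudes <- function(dp) {
  stopifnot(inherits(dp, "lv_dimparams"))
  c_ <- dp$c; d <- dp$d; f <- dp$f
  list(A1 = (1 - c_ * d) / c_^2,
       A2 = if (c_ * f > 1) (f - d)^2 / (4 * (c_ * f - 1)) else NA_real_)
}

#' Dose thresholds of host-directed constant therapy in original units
#'
#' The doses at which the forcing amplitude reaches the bifurcation
#' amplitudes:
#' \deqn{D_1 = \frac{r_x r_y (r_x - K_y\alpha_{xy})}{K_y \alpha_{xy}^2 |\beta_y|}, \qquad
#'       D_2 = \frac{r_x K_y (r_y - K_x\alpha_{yx})^2}
#'                  {4 |\beta_y| (K_y K_x \alpha_{xy}\alpha_{yx} - r_x r_y)},}
#' satisfying `forcing_amplitude(D1) = A1` and
#' `forcing_amplitude(D2) = A2` identically.
#'
#' @inheritParams forcing_amplitude
#' @return List with `D1` and `D2` (`D2` is `NA` when `cf <= 1`, where no
#'   saddle-node occurs).
#' @export
dose_thresholds_additive <- function(params, beta_y) {
  stopifnot(inherits(params, "lv_params"))
  if (beta_y >= 0)
    stop("host-directed additive therapy requires beta_y < 0")
  with(params, {
    if (alpha_xy == 0)
      stop("boundary case: alpha_xy = 0 gives an undefined D1")
    denom2 <- Ky * Kx * alpha_xy * alpha_yx - rx * ry
    D1 <- rx * ry * (rx - Ky * alpha_xy) / (Ky * alpha_xy^2 * abs(beta_y))
    D2 <- if (denom2 > 0) {
      rx * Ky * (ry - Kx * alpha_yx)^2 / (4 * abs(beta_y) * denom2)
    } else if (denom2 == 0) {
      stop("boundary case: cf = 1 gives an undefined D2")
    } else NA_real_
    list(D1 = D1, D2 = D2)
  })
}

#' Outcome planner for host-directed constant therapy
#'
#' Predicts the perturbed-system regime (starred labels, since the forced
#' system has its own equilibrium structure) reached under constant
#' host-directed forcing. From regime IV with `cf > 1`: `A > A2` gives
#' `I*`; for `A1 < A < A2`, `c(f-d) > 2(cf-1)` (interior pair outside the
#' positive quadrant) gives `I*` and `c(f-d) < 2(cf-1)` gives `III*`;
#' `A < A1` gives `II*`. From IV with `cf < 1`: `A > A1` gives `I*`, else
#' `II*`. From III: `A > A2` gives `I*`, else `III*`. From II: `A > A1`
#' gives `I*`, else `II*`. Since `(x, 0)` is never an equilibrium of the
#' forced system, the host population cannot vanish under this therapy.
#'
#' @param params an [lv_params] or [dimensionless_params] object.
#' @param beta_y,D host effect coefficient (negative) and dose; required
#'   (and used to compute `A`) when `params` is an [lv_params].
#' @param A forcing amplitude; supplied directly when `params` is an
#'   [dimensionless_params].
#' @param tol boundary tolerance.
#' @return An object of class `lv_add_plan`: baseline regime, `A`, `A1`,
#'   `A2`, dose thresholds `D1`/`D2` (original-units input only), the
#'   `Q`-point reports at `A`, and the predicted `outcome` label among
#'   `"I*"`, `"II*"`, `"III*"` (or `"DEGENERATE"` on a boundary).
#' @examples
#' dp <- dimensionless_params(1, 0.66, 1.1)  # regime IV, cf > 1
#' plan_outcome_additive(dp, A = 0.5)         # beyond A2: tumor-free I*
#' @export
plan_outcome_additive <- function(params, beta_y = NULL, D = NULL,
                                  A = NULL, tol = 1e-12) {
  doses <- NULL
  if (inherits(params, "lv_params")) {
    if (is.null(beta_y) || is.null(D))
      stop("supply beta_y and D with original-coordinate parameters")
    A <- forcing_amplitude(D, beta_y, params)
    doses <- dose_thresholds_additive(params, beta_y)
    dp <- to_dimensionless(params)
  } else if (inherits(params, "lv_dimparams")) {
    if (is.null(A)) stop("supply the forcing amplitude A")
    dp <- params
  } else stop("params must be lv_params or dimensionless_params")
  stopifnot(A >= 0)

  baseline <- classify_regime(dp)
  amp <- bifurcation_amplitudes(dp)
  A1 <- amp$A1; A2 <- amp$A2
  cf <- dp$c * dp$f
  near <- function(a, b) is.finite(b) && abs(a - b) <= tol * max(1, abs(b))

  outcome <- if (A <= tol) {
    baseline
  } else if (baseline == "I") {
    "I"  # no-op: boosting the host cannot worsen the tumor-free regime
  } else if (baseline == "IV" && cf > 1) {
    if (near(A, A2) || near(A, A1)) "DEGENERATE"
    else if (A > A2) "I*"
    else if (A > A1) {
      side <- dp$c * (dp$f - dp$d) - 2 * (cf - 1)
      if (abs(side) <= tol) "DEGENERATE" else if (side > 0) "I*" else "III*"
    } else "II*"
  } else if (baseline == "IV") {  # cf < 1
    if (near(A, A1)) "DEGENERATE" else if (A > A1) "I*" else "II*"
  } else if (baseline == "III") {
    if (near(A, A2)) "DEGENERATE" else if (A > A2) "I*" else "III*"
  } else if (baseline == "II") {
    if (near(A, A1)) "DEGENERATE" else if (A > A1) "I*" else "II*"
  } else "DEGENERATE"

  structure(list(baseline = baseline, A = A, A1 = A1, A2 = A2,
                 D = D, doses = doses,
                 q_points = q_equilibria(dp, A),
                 outcome = outcome,
                 host_persists = TRUE),
            class = "lv_add_plan")
}

#' @export
print.lv_add_plan <- function(x, ...) {
  cat(sprintf("Host-directed constant-therapy plan (baseline regime %s)\n",
              x$baseline))
  cat(sprintf("  A = %g; bifurcation amplitudes A1 = %g, A2 = %s\n",
              x$A, x$A1,
              if (is.na(x$A2)) "NA (cf <= 1)" else format(x$A2)))
  if (!is.null(x$doses))
    cat(sprintf("  dose thresholds: D1 = %g, D2 = %s\n", x$doses$D1,
                if (is.na(x$doses$D2)) "NA" else format(x$doses$D2)))
  cat(sprintf("  predicted outcome: %s\n", x$outcome))
  cat("  note: (x, 0) is never an equilibrium of the forced system;",
      "the host population cannot vanish\n")
  invisible(x)
}
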