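#' Vector field of the dimensionless system
#'
#' Right-hand side \eqn{\dot u = u - u^2 - c u v},
#' \eqn{\dot v = d v - v^2 - f u v + A}, where `A` is an (optionally
#' time-dependent) additive forcing of the host equation.
#'
#' @param u,v state components.
#' @param dp an [dimensionless_params] object.
#' @param A forcing value at the current time (scalar).
#' @return Numeric vector `c(du, dv)`.
#' @export
lv_rhs_dimensionless <- function(u, v, dp, A = 0) {
  stopifnot(inherits(dp, "lv_dimparams"))
  c(u - u^2 - dp$c * u * v,
    dp$d * v - v^2 - dp$f * u * v + A)
}

#' Vector field in original coordinates with optional therapy
#'
#' Implements the kinetic equations with the therapy term selected by the
#' mode of `therapy`: proportional (`- D beta x`, `- D beta y` per-capita),
#' constant additive (`- D beta`), or periodic additive
#' (`- D (1 - cos(omega t)) beta`). With `D = 0` (or `therapy = NULL`) all
#' modes coincide with the unperturbed equations.
#'
#' @param x,y state components.
#' @param params an [lv_params] object.
#' @param therapy an [therapy_spec] object or `NULL`.
#' @param t time in days (needed for periodic mode).
#' @return Numeric vector `c(dx, dy)`.
#' @export
lv_rhs_original <- function(x, y, params, therapy = NULL, t = 0) {
  stopifnot(inherits(params, "lv_params"))
  dx <- params$rx * x * (1 - x / params$Kx) - params$alpha_xy * x * y
  dy <- params$ry * y * (1 - y / params$Ky) - params$alpha_yx * y * x
  if (!is.null(therapy)) {
    if (!inherits(therapy, "lv_therapy"))
      stop("therapy must be built with therapy_spec()")
    dose <- switch(therapy$mode,
      proportional_constant = therapy$D,
      additive_constant     = therapy$D,
      periodic_additive     = therapy$D * (1 - cos(therapy$omega * t)),
      stop("unknown therapy mode: ", therapy$mode))
    if (therapy$mode == "proportional_constant") {
      dx <- dx - dose * therapy$beta_x * x
      dy <- dy - dose * therapy$beta_y * y
    } else {
      dx <- dx - dose * therapy$beta_x
      dy <- dy - dose * therapy$beta_y
    }
  }
  c(dx, dy)
}

# deSolve derivative functions (internal)
.deriv_original <- function(t, state, parms) {
  list(lv_rhs_original(state[1L], state[2L], parms$params, parms$therapy, t))
}

.deriv_dimensionless <- function(t, state, parms) {
  A <- 0
  fr <- parms$forcing
  if (!is.null(fr)) {
    A <- if (is.null(fr$omega)) fr$A else fr$A * (1 - cos(fr$omega * t))
  }
  list(lv_rhs_dimensionless(state[1L], state[2L], parms$dp, A))
}

#' Simulate tumor-host trajectories
#'
#' Integrates the model from a non-negative initial state, in original
#' coordinates (when `params` is an [lv_params], with an optional
#' [therapy_spec]) or in dimensionless coordinates (when `params` is an
#' [dimensionless_params], with an optional [dimensionless_forcing]).
#' Negative undershoot is not clipped: the positive quadrant is invariant
#' for the exact flow, so states are expected to stay non-negative to
#' solver tolerance.
#'
#' @param state0 numeric length-2 initial state, `c(x0, y0)` or `c(u0, v0)`.
#' @param params [lv_params] or [dimensionless_params].
#' @param therapy optional [therapy_spec] (original coordinates) or
#'   [dimensionless_forcing] (dimensionless coordinates).
#' @param t_end end of the integration interval (days, or dimensionless
#'   time).
#' @param n_out number of equally spaced output times (ignored when `times`
#'   is given).
#' @param times optional output time grid (strictly increasing, starting at
#'   `t0`).
#' @param t0 initial time.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param method a `deSolve` integration method; the default `"lsoda"`
#'   switches order/stiffness automatically, `"ode45"` gives a classical
#'   adaptive explicit Runge-Kutta pair.
#' @param maxsteps solver step budget per output interval.
#' @param ... further arguments for [deSolve::ode()].
#' @return An object of class `lv_trajectory`: a data frame with columns
#'   `t, x, y` (original) or `tau, u, v` (dimensionless), with the
#'   parameters, therapy and solver settings stored as attributes.
#' @examples
#' p <- lv_params(0.1, 0.075, 1, 1, 0.1237, 0.045)
#' tr <- lv_simulate(c(0.5, 0.5), p, t_end = 400, n_out = 101)
#' tail(tr, 2)  # tumor eliminated, host near capacity (regime I)
#' @export
lv_simulate <- function(state0, params, therapy = NULL,
                        t_end, n_out = 200L, times = NULL, t0 = 0,
                        rtol = 1e-8, atol = 1e-10, method = "lsoda",
                        maxsteps = 1e5, ...) {
  if (length(state0) != 2L || any(!is.finite(state0)))
    stop("state0 must be two finite numbers")
  if (any(state0 < 0))
    stop("initial state must be non-negative")
  if (is.null(times)) {
    if (missing(t_end) || t_end <= t0)
      stop("t_end must exceed t0")
    times <- seq(t0, t_end, length.out = max(2L, n_out))
  }
  if (any(diff(times) <= 0)) stop("output times must be strictly increasing")

  if (inherits(params, "lv_params")) {
    if (!is.null(therapy) && !inherits(therapy, "lv_therapy"))
      stop("original-coordinate simulation takes a therapy_spec()")
    fn <- .deriv_original
    parms <- list(params = params, therapy = therapy)
    cols <- c("t", "x", "y")
    coords <- "original"
  } else if (inherits(params, "lv_dimparams")) {
    if (!is.null(therapy) && !inherits(therapy, "lv_dimforcing"))
      stop("dimensionless simulation takes a dimensionless_forcing()")
    fn <- .deriv_dimensionless
    parms <- list(dp = params, forcing = therapy)
    cols <- c("tau", "u", "v")
    coords <- "dimensionless"
  } else stop("params must be lv_params or dimensionless_params")

  out <- deSolve::ode(y = unname(state0), times = times, func = fn,
                      parms = parms, rtol = rtol, atol = atol,
                      method = method, maxsteps = maxsteps, ...)
  out <- as.data.frame(out)
  names(out) <- cols
  if (nrow(out) < length(times) || any(!is.finite(as.matrix(out))))
    stop("ODE solver failed; last accepted time ",
         format(max(out[[1L]][stats::complete.cases(out)], na.rm = TRUE)))
  structure(out,
            class = c("lv_trajectory", "data.frame"),
            coordinates = coords, params = params, therapy = therapy,
            solver = list(method = method, rtol = rtol, atol = atol,
                          t_span = range(times), n_out = length(times)))
}

#' @export
print.lv_trajectory <- function(x, ...) {
  co <- attr(x, "coordinates")
  sv <- attr(x, "solver")
  cat(sprintf("LV trajectory (%s coordinates), %d samples on [%g, %g]\n",
              co, nrow(x), sv$t_span[1L], sv$t_span[2L]))
  cat(sprintf("  solver %s, rtol %g, atol %g\n", sv$method, sv$rtol, sv$atol))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...\n")
  invisible(x)
}

#' @export
plot.lv_trajectory <- function(x, which = c("time", "phase"), ...) {
  which <- match.arg(which)
  nm <- names(x)
  if (which == "time") {
    graphics::matplot(x[[1L]], as.matrix(x[, 2:3]), type = "l", lty = 1,
                      col = c("black", "blue"), xlab = nm[1L],
                      ylab = "population", ...)
    graphics::legend("topright", legend = nm[2:3], lty = 1,
                     col = c("black", "blue"), bty = "n")
  } else {
    graphics::plot(x[[2L]], x[[3L]], type = "l", xlab = nm[2L],
                   ylab = nm[3L], ...)
  }
  invisible(x)
}
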