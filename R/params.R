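#' Kinetic parameters of the tumor-host competitive Lotka-Volterra model
#'
#' Container for the six rate/capacity/interaction parameters of the
#' two-species competitive model
#' \deqn{\dot x = r_x x (1 - x/K_x) - \alpha_{xy} x y,}
#' \deqn{\dot y = r_y y (1 - y/K_y) - \alpha_{yx} y x,}
#' where \eqn{x} is the tumor population (or volume) and \eqn{y} the host
#' population. The interaction coefficient \eqn{\alpha_{xy}} bundles a pure
#' kill term \eqn{\delta_{xy}} with the shared-capacity crowding term, so the
#' biologically meaningful region has \eqn{\alpha_{xy} \ge r_x/K_x}
#' (equivalently \eqn{\delta_{xy} \ge 0}); that bound is only enforced when
#' `strict = TRUE` because several published regime examples sit below it.
#'
#' @param rx,ry intrinsic growth rates of tumor and host, per day.
#' @param Kx,Ky carrying capacities (cells, or cm\eqn{^3} when fitting
#'   volumes).
#' @param alpha_xy effect of the host on the tumor, per day per cell.
#' @param alpha_yx effect of the tumor on the host, per day per cell.
#' @param delta_xy,delta_yx optional pure kill coefficients; when omitted,
#'   `delta_xy` is derived as `alpha_xy - rx * gamma / Kx` (and analogously
#'   for `delta_yx`), which may be negative outside the strict region.
#' @param strict logical; enforce `alpha_xy >= rx/Kx`.
#'
#' @return An object of class `lv_params`: a list with the six parameters,
#'   the derived capacity ratio `gamma = Ky/Kx` and the kill coefficients.
#' @seealso [to_dimensionless()], [lv_simulate()], [classify_regime()]
#' @examples
#' p <- lv_params(rx = 0.1, ry = 0.075, Kx = 1, Ky = 1,
#'                alpha_xy = 0.1237, alpha_yx = 0.045)
#' to_dimensionless(p)
#' @export
lv_params <- function(rx, ry, Kx, Ky, alpha_xy, alpha_yx,
                      delta_xy = NULL, delta_yx = NULL, strict = FALSE) {
  vals <- c(rx = rx, ry = ry, Kx = Kx, Ky = Ky,
            alpha_xy = alpha_xy, alpha_yx = alpha_yx)
  if (any(!is.finite(vals)))
    stop("all kinetic parameters must be finite numbers")
  if (any(vals < 0))
    stop("kinetic parameters must be non-negative; got negative ",
         paste(names(vals)[vals < 0], collapse = ", "))
  if (Kx <= 0 || Ky <= 0)
    stop("carrying capacities must be positive")
  gamma <- Ky / Kx
  # crowding parts of the interactions under the shared-capacity reading
  # (x + gamma*y bounded by K = Kx); exact decomposition needs Kx = Ky
  if (is.null(delta_xy)) delta_xy <- alpha_xy - rx * gamma / Kx
  if (is.null(delta_yx)) delta_yx <- alpha_yx - ry / Kx
  if (strict && alpha_xy < rx / Kx - 1e-15)
    stop("strict mode: alpha_xy must satisfy alpha_xy >= rx/Kx (= ",
         format(rx / Kx), ")")
  structure(
    list(rx = rx, ry = ry, Kx = Kx, Ky = Ky,
         alpha_xy = alpha_xy, alpha_yx = alpha_yx,
         delta_xy = delta_xy, delta_yx = delta_yx, gamma = gamma),
    class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat("Tumor-host Lotka-Volterra kinetic parameters\n")
  cat(sprintf("  growth rates:     rx = %g, ry = %g  [1/day]\n", x$rx, x$ry))
  cat(sprintf("  capacities:       Kx = %g, Ky = %g  (gamma = %g)\n",
              x$Kx, x$Ky, x$gamma))
  cat(sprintf("  interactions:     alpha_xy = %g, alpha_yx = %g\n",
              x$alpha_xy, x$alpha_yx))
  if (x$rx > 0 && x$ry > 0) {
    dp <- to_dimensionless(x)
    cat(sprintf("  dimensionless:    c = %g, d = %g, f = %g  (regime %s)\n",
                dp$c, dp$d, dp$f, classify_regime(dp)))
  }
  invisible(x)
}

#' Dimensionless parameter triple (c, d, f)
#'
#' The rescaling \eqn{\tau = r_x t}, \eqn{x = K_x u},
#' \eqn{y = (r_x K_y / r_y) v} reduces the model to
#' \deqn{\dot u = u - u^2 - c\,u v, \qquad \dot v = d\,v - v^2 - f\,u v,}
#' with \eqn{c = K_y \alpha_{xy}/r_y}, \eqn{d = r_y/r_x},
#' \eqn{f = K_x \alpha_{yx}/r_x}. All regime logic depends only on this
#' triple.
#'
#' @param c,d,f positive dimensionless numbers.
#' @return An object of class `lv_dimparams`.
#' @export
dimensionless_params <- function(c, d, f) {
  if (any(!is.finite(c(c, d, f))) || any(c(c, d, f) <= 0))
    stop("c, d and f must be positive finite numbers")
  structure(list(c = c, d = d, f = f), class = "lv_dimparams")
}

#' @export
print.lv_dimparams <- function(x, ...) {
  cat(sprintf("Dimensionless LV parameters: c = %g, d = %g, f = %g\n",
              x$c, x$d, x$f))
  cat(sprintf("  cd = %g, cf = %g, f - d = %g  -> regime %s\n",
              x$c * x$d, x$c * x$f, x$f - x$d, classify_regime(x)))
  invisible(x)
}

#' Convert kinetic parameters to the dimensionless triple
#'
#' @param params an [lv_params] object with `rx > 0`, `ry > 0`.
#' @return An [dimensionless_params] object with
#'   `c = Ky*alpha_xy/ry`, `d = ry/rx`, `f = Kx*alpha_yx/rx`.
#' @export
to_dimensionless <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  if (params$rx <= 0 || params$ry <= 0)
    stop("to_dimensionless() requires rx > 0 and ry > 0")
  dimensionless_params(c = params$Ky * params$alpha_xy / params$ry,
                       d = params$ry / params$rx,
                       f = params$Kx * params$alpha_yx / params$rx)
}

#' Reconstruct kinetic parameters from a dimensionless triple
#'
#' The map to (c, d, f) loses the time scale `rx` and the two capacities,
#' which must be supplied; the remaining parameters are recovered exactly,
#' so `from_dimensionless(to_dimensionless(p), p$rx, p$Kx, p$Ky)`
#' round-trips to machine precision.
#'
#' @param dp an [dimensionless_params] object.
#' @param rx tumor growth rate setting the time scale, per day.
#' @param Kx,Ky carrying capacities.
#' @return An [lv_params] object.
#' @export
from_dimensionless <- function(dp, rx, Kx = 1, Ky = 1) {
  stopifnot(inherits(dp, "lv_dimparams"), rx > 0)
  ry <- dp$d * rx
  lv_params(rx = rx, ry = ry, Kx = Kx, Ky = Ky,
            alpha_xy = dp$c * ry / Ky,
            alpha_yx = dp$f * rx / Kx)
}

#' Original-to-dimensionless state transform
#'
#' Applies \eqn{\tau = r_x t}, \eqn{u = x/K_x},
#' \eqn{v = y\, r_y/(r_x K_y)} and its inverse.
#'
#' @param x,y populations in original coordinates (non-negative).
#' @param params an [lv_params] object.
#' @param t time in days.
#' @return `state_to_dimensionless()`: a list with `tau`, `u`, `v`;
#'   `state_from_dimensionless()`: a list with `t`, `x`, `y`.
#' @export
state_to_dimensionless <- function(x, y, params, t = 0) {
  stopifnot(inherits(params, "lv_params"))
  if (params$rx <= 0 || params$ry <= 0)
    stop("state transform requires rx > 0 and ry > 0")
  list(tau = params$rx * t,
       u = x / params$Kx,
       v = y * params$ry / (params$rx * params$Ky))
}

#' @rdname state_to_dimensionless
#' @param u,v populations in dimensionless coordinates.
#' @param tau dimensionless time.
#' @export
state_from_dimensionless <- function(u, v, params, tau = 0) {
  stopifnot(inherits(params, "lv_params"))
  if (params$rx <= 0 || params$ry <= 0)
    stop("state transform requires rx > 0 and ry > 0")
  list(t = tau / params$rx,
       x = u * params$Kx,
       y = v * params$rx * params$Ky / params$ry)
}

#' Therapy specification
#'
#' Describes one of the three perturbation (therapy) modes applied to the
#' kinetic equations, all built from a relative dose \eqn{D \ge 0}:
#'
#' * `"proportional_constant"`: continuous dose with per-capita effect,
#'   subtracting \eqn{D\beta_x x} and \eqn{D\beta_y y} (the betas are
#'   per-day rates). This rescales growth rates to \eqn{r_x - D\beta_x},
#'   \eqn{r_y - D\beta_y}.
#' * `"additive_constant"`: continuous dose destroying a constant number of
#'   cells per day, subtracting \eqn{D\beta_x} and \eqn{D\beta_y}
#'   (cells/day). Host-directed analysis requires `beta_x = 0`,
#'   `beta_y < 0`, i.e. the host is boosted at constant rate.
#' * `"periodic_additive"`: the additive effect modulated by
#'   \eqn{D(1-\cos\omega t)}, which is non-negative and averages to `D`
#'   over a forcing period.
#'
#' @param mode one of `"proportional_constant"`, `"additive_constant"`,
#'   `"periodic_additive"`.
#' @param D relative dose (applied dose over maximum permissible dose),
#'   dimensionless, `>= 0`.
#' @param beta_x,beta_y effect coefficients; per-day rates in proportional
#'   mode, cells/day in the additive modes.
#' @param omega forcing angular frequency, per day (required for
#'   `"periodic_additive"`).
#' @return An object of class `lv_therapy`.
#' @export
therapy_spec <- function(mode = c("proportional_constant",
                                  "additive_constant",
                                  "periodic_additive"),
                         D, beta_x = 0, beta_y, omega = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(D) || D < 0) stop("dose D must be non-negative")
  if (mode %in% c("additive_constant", "periodic_additive")) {
    if (beta_x != 0 || beta_y >= 0)
      stop("host-directed additive therapy requires beta_x = 0 and beta_y < 0")
  }
  if (mode == "periodic_additive") {
    if (is.null(omega) || !is.finite(omega) || omega <= 0)
      stop("periodic therapy requires a positive forcing frequency omega")
  }
  structure(list(mode = mode, D = D, beta_x = beta_x, beta_y = beta_y,
                 omega = omega),
            class = "lv_therapy")
}

#' @export
print.lv_therapy <- function(x, ...) {
  cat(sprintf("LV therapy: mode = %s, D = %g, beta_x = %g, beta_y = %g",
              x$mode, x$D, x$beta_x, x$beta_y))
  if (!is.null(x$omega)) cat(sprintf(", omega = %g /day", x$omega))
  cat("\n")
  invisible(x)
}

#' Dimensionless additive forcing
#'
#' Forcing applied to the host equation of the dimensionless system:
#' constant `A` when `omega` is `NULL`, or `A * (1 - cos(omega * tau))`
#' for periodic forcing in dimensionless time.
#'
#' @param A non-negative forcing amplitude.
#' @param omega dimensionless forcing frequency, or `NULL` for constant
#'   forcing.
#' @return An object of class `lv_dimforcing`.
#' @export
dimensionless_forcing <- function(A, omega = NULL) {
  if (!is.finite(A) || A < 0) stop("forcing amplitude A must be >= 0")
  if (!is.null(omega) && (!is.finite(omega) || omega <= 0))
    stop("omega must be positive (or NULL for constant forcing)")
  structure(list(A = A, omega = omega), class = "lv_dimforcing")
}
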