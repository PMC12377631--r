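#' One-dimensional potential of the particle reduction
#'
#' Eliminating the host variable turns the unperturbed dimensionless system
#' into the motion of a damped particle in the quartic potential defined by
#' \deqn{-V'(u) = (1/c - d)\,u + (d + f - 2/c)\,u^2 + (1/c - f)\,u^3,}
#' normalised here by `V(0) = 0`. Its extrema are `u1* = 0`, `u2* = 1` and
#' `u3* = (1 - cd)/(1 - cf)` (absent at `cf = 1`); a minimum of `V`
#' corresponds to a stable rest point of the tumor component
#' (`u1*` for `cd > 1`, `u2*` for `f > d`, `u3*` for `f < d`), and the
#' pattern of minima/maxima distinguishes six sub-cases across the four
#' regimes, switching with the sign of `cf - 1` (quartic opens upward for
#' `cf > 1`).
#'
#' @param dp an [dimensionless_params] object.
#' @param tol tolerance for the flat-curvature call.
#' @return An object of class `lv_potential`: list with `dimparams`,
#'   `coefficients` (of \eqn{V(u)=a_2u^2+a_3u^3+a_4u^4}), `extrema`
#'   (data frame `u`, `curvature`, `type`), `case_label`, and function
#'   slots `V(u)`, `dVdu(u)`, `d2Vdu2(u)`.
#' @export
potential_profile <- function(dp, tol = 1e-12) {
  stopifnot(inherits(dp, "lv_dimparams"))
  c_ <- dp$c; d <- dp$d; f <- dp$f
  # -dV/du = b1 u + b2 u^2 + b3 u^3
  b1 <- 1 / c_ - d
  b2 <- d + f - 2 / c_
  b3 <- 1 / c_ - f
  a <- c(a2 = -b1 / 2, a3 = -b2 / 3, a4 = -b3 / 4)
  V <- function(u) unname(a[1L] * u^2 + a[2L] * u^3 + a[3L] * u^4)
  dV <- function(u) -(b1 * u + b2 * u^2 + b3 * u^3)
  d2V <- function(u) -(b1 + 2 * b2 * u + 3 * b3 * u^2)

  us <- c(0, 1)
  if (abs(c_ * f - 1) > tol) us <- c(us, (1 - c_ * d) / (1 - c_ * f))
  curv <- d2V(us)
  type <- ifelse(abs(curv) <= tol, "degenerate",
                 ifelse(curv > 0, "min", "max"))
  extrema <- data.frame(u = us, curvature = curv, type = type,
                        row.names = paste0("u", seq_along(us), "*"))

  regime <- classify_regime(dp)
  sub <- if (regime %in% c("I", "IV")) {
    if (c_ * f > 1) " (cf > 1)" else " (cf < 1)"
  } else ""
  case_label <- if (regime == "DEGENERATE") "DEGENERATE"
                else paste0(regime, sub)

  structure(list(dimparams = dp, coefficients = a, extrema = extrema,
                 case_label = case_label, V = V, dVdu = dV, d2Vdu2 = d2V),
            class = "lv_potential")
}

#' @export
print.lv_potential <- function(x, ...) {
  a <- x$coefficients
  cat(sprintf("Particle potential V(u) = %.6g u^2 + %.6g u^3 + %.6g u^4  [case %s]\n",
              a[1L], a[2L], a[3L], x$case_label))
  print(x$extrema)
  invisible(x)
}

#' @export
plot.lv_potential <- function(x, from = NULL, to = NULL, n = 400L, ...) {
  us <- x$extrema$u
  if (is.null(from)) from <- min(-0.2, min(us) - 0.3)
  if (is.null(to)) to <- max(1.4, max(us) + 0.3)
  grid <- seq(from, to, length.out = n)
  graphics::plot(grid, x$V(grid), type = "l", xlab = "u", ylab = "V(u)", ...)
  graphics::points(us, x$V(us),
                   pch = ifelse(x$extrema$type == "min", 19, 1))
  invisible(x)
}

#' Characteristic frequency at a potential minimum
#'
#' The small-oscillation (proper) frequency around a stable rest point of
#' the particle reduction, \eqn{\Omega = \sqrt{V''(u^*)}}, in dimensionless
#' angular-frequency units (multiply by `rx` for per-day units). At
#' `u* = 1` this reduces to \eqn{\Omega = \sqrt{f - d}}, the relevant value
#' for the tumor-dominance regime.
#'
#' @param profile an [potential_profile()] result.
#' @param u_star location of a minimum of `V` (matched against the profile
#'   extrema within `tol`).
#' @param tol matching tolerance.
#' @return The dimensionless angular frequency `Omega`.
#' @export
characteristic_frequency <- function(profile, u_star, tol = 1e-8) {
  stopifnot(inherits(profile, "lv_potential"))
  i <- which(abs(profile$extrema$u - u_star) <= tol)
  if (length(i) == 0L)
    stop("u_star = ", format(u_star), " is not an extremum of V")
  curv <- profile$extrema$curvature[i[1L]]
  if (curv < 0)
    stop("V has negative curvature at u* = ", format(u_star),
         " (a maximum); Omega is defined only at minima")
  sqrt(curv)
}
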