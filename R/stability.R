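#' Jacobian of the dimensionless vector field
#'
#' Analytic Jacobian of the (possibly additively forced) dimensionless
#' system; additive forcing of the host equation does not enter the
#' Jacobian.
#'
#' @param u,v evaluation point.
#' @param dp an [dimensionless_params] object.
#' @return A 2x2 numeric matrix.
#' @export
lv_jacobian <- function(u, v, dp) {
  stopifnot(inherits(dp, "lv_dimparams"))
  matrix(c(1 - 2 * u - dp$c * v, -dp$c * u,
           -dp$f * v, dp$d - 2 * v - dp$f * u),
         nrow = 2L, byrow = TRUE)
}

# classify a fixed point from its eigenvalues (internal)
.stability_class <- function(ev, tol = 1e-9) {
  re <- Re(ev)
  if (any(abs(re) < tol)) return("degenerate")
  if (any(abs(Im(ev)) > tol)) {
    if (all(re < 0)) "stable spiral" else "unstable spiral"
  } else {
    if (all(re < 0)) "stable node"
    else if (all(re > 0)) "unstable node"
    else "saddle"
  }
}

.equilibrium_report <- function(label, loc, dp, tol = 1e-9) {
  ev <- eigen(lv_jacobian(loc[1L], loc[2L], dp), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(label = label, location = loc, eigenvalues = ev,
       stability_class = .stability_class(ev, tol),
       physical = all(loc >= -tol))
}

#' Equilibria of the unperturbed dimensionless system
#'
#' Returns the four fixed points `P1 = (0,0)`, `P2 = (0,d)`, `P3 = (1,0)`
#' and the coexistence point `P4 = ((1-cd)/(1-cf), (d-f)/(1-cf))`
#' (absent when `cf = 1`), each with eigenvalues computed numerically from
#' the analytic Jacobian and a stability class.
#'
#' @param dp an [dimensionless_params] object.
#' @param tol tolerance used for the degeneracy/physicality calls.
#' @return An object of class `lv_equilibria`: a named list of equilibrium
#'   reports (fields `label`, `location`, `eigenvalues`,
#'   `stability_class`, `physical`).
#' @export
equilibria <- function(dp, tol = 1e-9) {
  stopifnot(inherits(dp, "lv_dimparams"))
  c_ <- dp$c; d <- dp$d; f <- dp$f
  pts <- list(P1 = c(0, 0), P2 = c(0, d), P3 = c(1, 0))
  if (abs(c_ * f - 1) > tol) {
    pts$P4 <- c((1 - c_ * d) / (1 - c_ * f), (d - f) / (1 - c_ * f))
  }
  out <- lapply(names(pts), function(nm)
    .equilibrium_report(nm, pts[[nm]], dp, tol))
  names(out) <- names(pts)
  structure(out, class = "lv_equilibria", dimparams = dp,
            P4_at_infinity = abs(c_ * f - 1) <= tol)
}

#' @export
print.lv_equilibria <- function(x, ...) {
  cat("Equilibria of the dimensionless LV system\n")
  for (e in x) {
    cat(sprintf("  %s = (%.6g, %.6g): %s  [lambda = %s]%s\n",
                e$label, e$location[1L], e$location[2L], e$stability_class,
                paste(format(e$eigenvalues, digits = 4), collapse = ", "),
                if (e$physical) "" else "  (non-physical)"))
  }
  if (isTRUE(attr(x, "P4_at_infinity")))
    cat("  P4 absent (cf = 1: coexistence point at infinity)\n")
  invisible(x)
}

#' Classify the dynamical regime from (c, d, f)
#'
#' The four regimes of the unperturbed system are
#' * `I`:   `cd > 1`, `f < d` - tumor elimination (all trajectories to P2),
#' * `II`:  `cf < 1`, `cd < 1`, `f < d` - stable coexistence at P4,
#' * `III`: `cf > 1`, `cd > 1`, `f > d` - bistability, basins split by the
#'   separatrix through the saddle P4,
#' * `IV`:  `cd < 1`, `f > d` - tumor dominance (all trajectories to P3).
#'
#' Points within `tol` of the boundary manifolds `cd = 1`, `f = d` or
#' `cf = 1` are reported as `"DEGENERATE"` rather than silently assigned
#' to a side.
#'
#' @param dp an [dimensionless_params] object (or [lv_params], converted
#'   first).
#' @param tol boundary tolerance.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"DEGENERATE"`.
#' @export
classify_regime <- function(dp, tol = 1e-12) {
  if (inherits(dp, "lv_params")) dp <- to_dimensionless(dp)
  stopifnot(inherits(dp, "lv_dimparams"))
  cd <- dp$c * dp$d; cf <- dp$c * dp$f; fd <- dp$f - dp$d
  if (abs(cd - 1) <= tol || abs(cf - 1) <= tol || abs(fd) <= tol)
    return("DEGENERATE")
  if (cd > 1 && fd < 0) return("I")
  if (cf < 1 && cd < 1 && fd < 0) return("II")
  if (cf > 1 && cd > 1 && fd > 0) return("III")
  if (cd < 1 && fd > 0) return("IV")
  "DEGENERATE"
}

#' Separatrix of the bistable regime
#'
#' In regime III the coexistence point P4 is a saddle whose stable manifold
#' divides the positive quadrant into the basins of P2 (host wins) and P3
#' (tumor wins). The two branches of the manifold are traced by integrating
#' the vector field backward in time from `P4 +/- eps * w_s`, where `w_s`
#' is the stable eigenvector.
#'
#' @param dp an [dimensionless_params] object in regime III.
#' @param t_max backward-integration horizon (dimensionless time).
#' @param n number of sample points per branch (uniform in time).
#' @param eps initial offset along the stable eigenvector.
#' @param arc_length optional cap: each branch is truncated at this
#'   cumulative arc length.
#' @param box clipping box `c(umin, umax, vmin, vmax)`; points outside are
#'   dropped.
#' @return An object of class `lv_separatrix`: a data frame with columns
#'   `branch` (1 or 2), `u`, `v`, ordered outward from P4, with P4 stored
#'   as an attribute.
#' @export
separatrix <- function(dp, t_max = 60, n = 400L, eps = 1e-6,
                       arc_length = NULL, box = c(-0.1, 3, -0.1, 3)) {
  stopifnot(inherits(dp, "lv_dimparams"))
  if (classify_regime(dp) != "III")
    stop("separatrix() is defined only in regime III (P4 saddle)")
  eq <- equilibria(dp)
  P4 <- eq$P4$location
  J <- lv_jacobian(P4[1L], P4[2L], dp)
  es <- eigen(J)
  i_stable <- which(Re(es$values) < 0)
  if (length(i_stable) != 1L) stop("P4 is not a saddle")
  ws <- Re(es$vectors[, i_stable])
  ws <- ws / sqrt(sum(ws^2))

  backward <- function(t, state, parms)
    list(-lv_rhs_dimensionless(state[1L], state[2L], parms, 0))
  # halt the backward integration when the branch exits the box, so the
  # solver does not grind against a slow (reversed-time) source
  exit_box <- function(t, state, parms)
    min(state[1L] - box[1L], box[2L] - state[1L],
        state[2L] - box[3L], box[4L] - state[2L])
  trace_branch <- function(sgn) {
    st0 <- P4 + sgn * eps * ws
    tt <- seq(0, t_max, length.out = n)
    out <- deSolve::lsodar(unname(st0), tt, backward, dp,
                           rtol = 1e-10, atol = 1e-12,
                           rootfunc = exit_box)
    m <- as.data.frame(out)[, 2:3]
    names(m) <- c("u", "v")
    keep <- is.finite(m$u) & is.finite(m$v)
    m <- m[keep, , drop = FALSE]
    if (!is.null(arc_length)) {
      s <- c(0, cumsum(sqrt(diff(m$u)^2 + diff(m$v)^2)))
      m <- m[s <= arc_length, , drop = FALSE]
    }
    m
  }
  b1 <- trace_branch(+1); b1$branch <- 1L
  b2 <- trace_branch(-1); b2$branch <- 2L
  out <- rbind(b1, b2)[, c("branch", "u", "v")]
  structure(out, class = c("lv_separatrix", "data.frame"),
            P4 = P4, dimparams = dp)
}

#' @export
print.lv_separatrix <- function(x, ...) {
  P4 <- attr(x, "P4")
  cat(sprintf("Regime III separatrix through P4 = (%.6g, %.6g); %d points (%d + %d)\n",
              P4[1L], P4[2L], nrow(x), sum(x$branch == 1L), sum(x$branch == 2L)))
  invisible(x)
}

#' Dulac certificate for the absence of closed orbits
#'
#' With the Dulac function \eqn{R = u^m v^n},
#' \eqn{m = (cf + f - 2)/(1 - cf)}, \eqn{n = (cf + c - 2)/(1 - cf)},
#' the divergence of the rescaled field is
#' \eqn{\Gamma = u^m v^n \kappa} with
#' \eqn{\kappa = (cd - 1 + f - d)/(1 - cf)}. When \eqn{\kappa \ne 0},
#' \eqn{\Gamma} keeps one sign inside the open quadrant, so no closed orbit
#' lies there; the certificate is inconclusive in the degenerate case
#' \eqn{cd - 1 = d - f}, where P4 acquires purely imaginary eigenvalues for
#' `cf > 1`.
#'
#' @param dp an [dimensionless_params] object with `cf != 1`.
#' @param tol degeneracy tolerance.
#' @return An object of class `lv_dulac`: list with `m`, `n`,
#'   `sign_coefficient` (kappa), `conclusive`, `degenerate_case`.
#' @export
dulac_certificate <- function(dp, tol = 1e-12) {
  stopifnot(inherits(dp, "lv_dimparams"))
  c_ <- dp$c; d <- dp$d; f <- dp$f
  if (abs(c_ * f - 1) <= tol)
    stop("Dulac exponents are undefined at cf = 1")
  m <- (c_ * f + f - 2) / (1 - c_ * f)
  n <- (c_ * f + c_ - 2) / (1 - c_ * f)
  kappa <- (c_ * d - 1 + f - d) / (1 - c_ * f)
  degenerate <- abs((c_ * d - 1) - (d - f)) <= tol
  structure(list(m = m, n = n, sign_coefficient = kappa,
                 conclusive = !degenerate && abs(kappa) > tol,
                 degenerate_case = degenerate),
            class = "lv_dulac")
}

#' @export
print.lv_dulac <- function(x, ...) {
  cat(sprintf("Dulac certificate R = u^m v^n: m = %.6g, n = %.6g\n", x$m, x$n))
  cat(sprintf("  sign coefficient kappa = %.6g -> %s\n", x$sign_coefficient,
              if (x$degenerate_case) "degenerate case (cd - 1 = d - f)"
              else if (x$conclusive) "no closed orbits in the open quadrant"
              else "inconclusive"))
  invisible(x)
}
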