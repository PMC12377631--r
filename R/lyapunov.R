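#' Settings for the tangent-vector renormalization (Benettin) method
#'
#' @param tau_renorm interval between tangent-vector renormalizations,
#'   dimensionless time.
#' @param h fixed integration step of the classical 4th-order Runge-Kutta
#'   scheme; must divide `tau_renorm` (enforced by rounding).
#' @param n_steps number of renormalizations, so the total integration
#'   time is `n_steps * tau_renorm`.
#' @param d0 initial tangent-vector norm; the running exponents are
#'   invariant under its choice because the variational system is linear.
#' @param tol convergence tolerance: the spread of the running maximum
#'   exponent over the last quartile of renormalization steps.
#' @return An object of class `lv_lyap_settings`.
#' @export
lyapunov_settings <- function(tau_renorm = 0.1, h = 0.02, n_steps = 3000L,
                              d0 = 1, tol = 1e-3) {
  if (tau_renorm <= 0) stop("tau_renorm must be positive")
  if (h <= 0 || h > tau_renorm) stop("need 0 < h <= tau_renorm")
  m <- max(1L, as.integer(round(tau_renorm / h)))
  structure(list(tau_renorm = tau_renorm, h = tau_renorm / m,
                 steps_per_interval = m, n_steps = as.integer(n_steps),
                 d0 = d0, tol = tol),
            class = "lv_lyap_settings")
}

# Benettin renormalization loop for a planar field (internal).
# field(t, z) returns c(dz1, dz2); jac(t, z) returns a 2x2 matrix.
# The reference state and two tangent vectors are advanced jointly with a
# fixed-step classical RK4; every tau the first tangent's stretch is
# logged and reset to norm d0, and the second is orthogonalized against
# the first before its own stretch is logged and reset.
.benettin <- function(field, jac, state0, settings, t0 = 0) {
  s <- settings
  z <- as.numeric(state0)
  d0 <- s$d0
  w1 <- c(d0, 0); w2 <- c(0, d0)
  h <- s$h; m <- s$steps_per_interval; n <- s$n_steps
  log1 <- numeric(n); log2 <- numeric(n)
  ref <- matrix(NA_real_, nrow = n, ncol = 3L,
                dimnames = list(NULL, c("t", "z1", "z2")))
  t <- t0

  deriv <- function(t, z, w1, w2) {
    J <- jac(t, z)
    list(dz = field(t, z), dw1 = J %*% w1, dw2 = J %*% w2)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      k1 <- deriv(t, z, w1, w2)
      k2 <- deriv(t + h / 2, z + h / 2 * k1$dz,
                  w1 + h / 2 * k1$dw1, w2 + h / 2 * k1$dw2)
      k3 <- deriv(t + h / 2, z + h / 2 * k2$dz,
                  w1 + h / 2 * k2$dw1, w2 + h / 2 * k2$dw2)
      k4 <- deriv(t + h, z + h * k3$dz,
                  w1 + h * k3$dw1, w2 + h * k3$dw2)
      z  <- z  + h / 6 * (k1$dz  + 2 * k2$dz  + 2 * k3$dz  + k4$dz)
      w1 <- as.numeric(w1 + h / 6 * (k1$dw1 + 2 * k2$dw1 + 2 * k3$dw1 + k4$dw1))
      w2 <- as.numeric(w2 + h / 6 * (k1$dw2 + 2 * k2$dw2 + 2 * k3$dw2 + k4$dw2))
      t <- t + h
    }
    if (any(!is.finite(c(z, w1, w2))) || sum(z^2) > 1e16)
      stop("trajectory escape/overflow at t = ", format(t),
           "; state = (", paste(format(z), collapse = ", "), ")")
    d1 <- sqrt(sum(w1^2))
    log1[i] <- log(d1 / d0)
    w1 <- w1 * (d0 / d1)
    u1 <- w1 / d0
    w2o <- w2 - sum(w2 * u1) * u1
    d2 <- sqrt(sum(w2o^2))
    log2[i] <- log(d2 / d0)
    w2 <- w2o * (d0 / d2)
    ref[i, ] <- c(t, z)
  }
  tau <- s$tau_renorm
  list(sigma1 = cumsum(log1) / (tau * seq_len(n)),
       sigma2 = cumsum(log2) / (tau * seq_len(n)),
       ref = ref)
}

# field/jacobian closures for the forced dimensionless system (internal)
.forced_field <- function(dp, A, omega) {
  force(dp); force(A); force(omega)
  periodic <- !is.null(omega) && omega > 0
  list(
    field = function(t, z) {
      Ft <- if (periodic) A * (1 - cos(omega * t)) else A
      c(z[1L] - z[1L]^2 - dp$c * z[1L] * z[2L],
        dp$d * z[2L] - z[2L]^2 - dp$f * z[1L] * z[2L] + Ft)
    },
    jac = function(t, z) lv_jacobian(z[1L], z[2L], dp))
}

#' Lyapunov spectrum of the (forced) dimensionless system
#'
#' Computes the two Lyapunov characteristic exponents of the dimensionless
#' tumor-host system with additive host forcing `A (1 - cos(omega tau))`
#' (constant `A` when `omega = 0`), by integrating the reference
#' trajectory together with two tangent vectors under the variational
#' (linearized) equations and renormalizing every `tau_renorm`: the raw
#' stretch of the first tangent yields the maximum exponent, the
#' orthogonalized complement yields the second, and the running estimate
#' after n renormalizations is
#' \deqn{\sigma_n = \frac{1}{n\tau}\sum_{i=1}^n \ln(d_i/d_0).}
#' A negative maximum exponent certifies non-chaotic, contracting
#' dynamics.
#'
#' @param dp an [dimensionless_params] object.
#' @param A non-negative forcing amplitude.
#' @param omega dimensionless forcing frequency (0 for constant forcing).
#' @param settings an [lyapunov_settings()] object.
#' @param state0 initial state in the open positive quadrant.
#' @return An object of class `lv_lyapunov`: running sequences
#'   `sigma1_seq`, `sigma2_seq`, the converged `spectrum` (descending),
#'   `max_exponent`, a `converged` flag (last-quartile drift below the
#'   settings tolerance), the reference trajectory at renormalization
#'   times, and the parameter/settings provenance.
#' @examples
#' dp <- dimensionless_params(1.65, 0.75, 0.45)      # regime I
#' res <- lyapunov_spectrum(dp, settings = lyapunov_settings(n_steps = 1500),
#'                          state0 = c(1e-3, 0.75))
#' res$spectrum   # close to the eigenvalues (1 - cd, -d) of the stable node
#' @export
lyapunov_spectrum <- function(dp, A = 0, omega = 0,
                              settings = lyapunov_settings(),
                              state0 = c(0.5, 0.5)) {
  stopifnot(inherits(dp, "lv_dimparams"),
            inherits(settings, "lv_lyap_settings"), A >= 0)
  if (any(state0 <= 0))
    stop("state0 must lie in the open positive quadrant")
  fj <- .forced_field(dp, A, if (omega > 0) omega else NULL)
  bl <- .benettin(fj$field, fj$jac, state0, settings)
  n <- settings$n_steps
  last_q <- seq.int(max(1L, floor(3 * n / 4)), n)
  drift <- diff(range(bl$sigma1[last_q]))
  spec <- sort(c(bl$sigma1[n], bl$sigma2[n]), decreasing = TRUE)
  structure(list(sigma1_seq = bl$sigma1, sigma2_seq = bl$sigma2,
                 spectrum = spec, max_exponent = spec[1L],
                 converged = drift < settings$tol, drift = drift,
                 ref_trajectory = bl$ref,
                 params = c(c = dp$c, d = dp$d, f = dp$f, A = A,
                            omega = omega),
                 settings = settings),
            class = "lv_lyapunov")
}

#' @export
print.lv_lyapunov <- function(x, ...) {
  p <- x$params
  cat(sprintf("Lyapunov spectrum at (c, d, f, A, omega) = (%g, %g, %g, %g, %g)\n",
              p[1L], p[2L], p[3L], p[4L], p[5L]))
  cat(sprintf("  exponents: %.6g, %.6g  (n = %d renormalizations, tau = %g, h = %g)\n",
              x$spectrum[1L], x$spectrum[2L], x$settings$n_steps,
              x$settings$tau_renorm, x$settings$h))
  cat(sprintf("  converged: %s (last-quartile drift %.2g)\n",
              x$converged, x$drift))
  invisible(x)
}

#' Running Lyapunov-exponent sequence
#'
#' Extracts the running estimates \eqn{\sigma_n} for convergence plots.
#'
#' @param result an [lyapunov_spectrum()] result.
#' @return A data frame with columns `n`, `sigma1`, `sigma2`.
#' @export
sigma_sequence <- function(result) {
  stopifnot(inherits(result, "lv_lyapunov"))
  data.frame(n = seq_along(result$sigma1_seq),
             sigma1 = result$sigma1_seq,
             sigma2 = result$sigma2_seq)
}

#' Monte-Carlo search for local maxima of the maximum Lyapunov exponent
#'
#' Random search over the five-dimensional parameter box
#' `(c, d, f, A, omega)` followed by a local refinement phase in a
#' shrunken box around the incumbent. Deterministic for a fixed seed.
#'
#' @param box named list of length-2 ranges for `c`, `d`, `f`, `A`,
#'   `omega`.
#' @param budget total number of spectrum evaluations (`>= 1`).
#' @param seed integer seed.
#' @param settings an [lyapunov_settings()] object.
#' @param state0 initial state passed to each evaluation.
#' @param refine_frac fraction of the budget spent on refinement.
#' @param shrink width of the refinement box relative to the full box.
#' @return List with `best` (named parameter vector), `result` (the
#'   [lyapunov_spectrum()] object at the best point) and `evaluations`
#'   (data frame of all evaluated points and their maximum exponents).
#' @export
search_max_lce <- function(box = list(c = c(0.5, 2), d = c(0.5, 1.5),
                                      f = c(0.5, 1.5), A = c(0, 0.5),
                                      omega = c(0.05, 5)),
                           budget = 40L, seed = 1L,
                           settings = lyapunov_settings(),
                           state0 = c(0.5, 0.5),
                           refine_frac = 0.4, shrink = 0.25) {
  stopifnot(budget >= 1)
  nm <- c("c", "d", "f", "A", "omega")
  if (!all(nm %in% names(box))) stop("box must bound c, d, f, A, omega")
  lo <- vapply(box[nm], `[`, numeric(1L), 1L)
  hi <- vapply(box[nm], `[`, numeric(1L), 2L)
  if (any(!is.finite(c(lo, hi))) || any(hi < lo))
    stop("box bounds must be finite with upper >= lower")
  set.seed(seed)

  eval_pt <- function(p) {
    tryCatch(lyapunov_spectrum(
      dimensionless_params(p[1L], p[2L], p[3L]),
      A = p[4L], omega = p[5L], settings = settings,
      state0 = state0)$max_exponent,
      error = function(e) NA_real_)
  }
  draw <- function(n, l, u)
    matrix(stats::runif(n * 5L, rep(l, each = n), rep(u, each = n)),
           ncol = 5L, dimnames = list(NULL, nm))

  n1 <- max(1L, ceiling(budget * (1 - refine_frac)))
  pts <- draw(n1, lo, hi)
  vals <- apply(pts, 1L, eval_pt)
  n2 <- budget - n1
  if (n2 > 0L && any(is.finite(vals))) {
    best <- pts[which.max(vals), ]
    half <- shrink * (hi - lo) / 2
    l2 <- pmax(lo, best - half); u2 <- pmin(hi, best + half)
    pts2 <- draw(n2, l2, u2)
    vals2 <- apply(pts2, 1L, eval_pt)
    pts <- rbind(pts, pts2); vals <- c(vals, vals2)
  }
  if (!any(is.finite(vals))) stop("all spectrum evaluations failed")
  i <- which.max(vals)
  best <- pts[i, ]
  list(best = best,
       result = lyapunov_spectrum(
         dimensionless_params(best[1L], best[2L], best[3L]),
         A = best[4L], omega = best[5L], settings = settings,
         state0 = state0),
       evaluations = data.frame(pts, max_exponent = vals))
}

#' One-at-a-time sweep of the maximum Lyapunov exponent
#'
#' Varies one of `c`, `d`, `f`, `A`, `omega` over a grid while holding the
#' other four at the base point, the standard protocol for mapping how
#' the maximum exponent responds to each parameter (a discontinuity is
#' expected where the sweep crosses the saddle-node amplitude `A2`).
#'
#' @param base named vector or list with entries `c`, `d`, `f`, `A`,
#'   `omega`.
#' @param param which entry to sweep.
#' @param grid values for the swept parameter.
#' @param settings an [lyapunov_settings()] object.
#' @param state0 initial state.
#' @return Data frame with columns `value`, `max_exponent`,
#'   `second_exponent` (failures yield `NA` rows).
#' @export
lce_parameter_sweep <- function(base, param, grid,
                                settings = lyapunov_settings(),
                                state0 = c(0.5, 0.5)) {
  base <- unlist(base)[c("c", "d", "f", "A", "omega")]
  if (any(is.na(base))) stop("base must provide c, d, f, A, omega")
  if (!param %in% names(base)) stop("param must be one of c, d, f, A, omega")
  rows <- lapply(grid, function(v) {
    p <- base; p[param] <- v
    res <- tryCatch(lyapunov_spectrum(
      dimensionless_params(p["c"], p["d"], p["f"]),
      A = p["A"], omega = p["omega"], settings = settings,
      state0 = state0),
      error = function(e) NULL)
    if (is.null(res))
      data.frame(value = v, max_exponent = NA_real_,
                 second_exponent = NA_real_)
    else
      data.frame(value = v, max_exponent = res$spectrum[1L],
                 second_exponent = res$spectrum[2L])
  })
  do.call(rbind, rows)
}
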