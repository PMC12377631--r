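# shared helpers for the test suite

fx <- lv_fixtures()

# random dimensionless triples, optionally conditioned on a regime
random_triples <- function(n, seed = 1, regime = NULL) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    dp <- dimensionless_params(runif(1, 0.3, 2), runif(1, 0.3, 1.6),
                               runif(1, 0.3, 1.6))
    if (is.null(regime) || classify_regime(dp) == regime) {
      i <- i + 1L
      out[[i]] <- dp
    }
  }
  out
}

# finite-difference Jacobian of the dimensionless field (independent
# oracle; central differences are exact for this quadratic field, so a
# larger step only reduces roundoff)
fd_jacobian <- function(u, v, dp, h = 1e-4) {
  f <- function(u, v) lv_rhs_dimensionless(u, v, dp)
  cbind((f(u + h, v) - f(u - h, v)) / (2 * h),
        (f(u, v + h) - f(u, v - h)) / (2 * h))
}

# brute-force Hausdorff distance (independent of the packaged routine)
bf_hausdorff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  dmat <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
  dmat[dmat < 0] <- 0
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# fast settings for unit-level Lyapunov runs
quick_lyap <- function(n_steps = 1000L) lyapunov_settings(n_steps = n_steps)
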