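# Independent oracles used to cross-check the package's implementations.
# These deliberately re-derive results from first principles (closed forms,
# normal equations, fixed-step Euler) rather than calling the code they check.

# Closed-form OLS via mean/covariance formulas.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ss_tot <- sum((y - mean(y))^2)
  s2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot == 0) 0 else 1 - sum(res^2) / ss_tot,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)))
}

# Dense normal-equations least squares.
normal_eq_oracle <- function(B, y) {
  drop(solve(crossprod(B), crossprod(B, y)))
}

# Fixed-step forward Euler for the Type II kinetic system, with the rate
# expressions written out inline (independent of the package's RHS).
euler_oracle <- function(S0, O2, phi, t_end, dt,
                         xi = 51e-3, beta = 11.9, delta = 33,
                         sigma = 1.7e-5, tau_delta = 9.4e-6,
                         k7 = 0, A = 0, clamped = TRUE) {
  O2rx <- 0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    f <- O2 / (O2 + beta)
    g <- sigma * (S0 + delta)
    r0 <- xi * f * phi * S0
    dS0 <- -r0 * g / (g + 1)
    dO2 <- if (clamped) 0 else -r0 * (g + k7 * A * tau_delta) / (g + 1)
    dO2rx <- r0 / (g + 1)
    S0 <- S0 + dt * dS0
    O2 <- O2 + dt * dO2
    O2rx <- O2rx + dt * dO2rx
  }
  c(S0 = S0, O2 = O2, O2rx = O2rx)
}

# Small deterministic basis for unmixing tests.
toy_basis <- function(n = 64) {
  wl <- seq(1200, 1600, length.out = n)
  o2 <- exp(-(wl - 1270)^2 / (2 * (20 / 2.3548)^2))
  phos <- exp(-(wl - 1200) / 200)
  bg <- exp(-(wl - 1200) / 30)
  basis_matrix(wl, cbind(o2 = o2 / max(o2), phos = phos / max(phos),
                         bg = bg / max(bg)))
}
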