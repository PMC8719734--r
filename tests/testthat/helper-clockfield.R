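# Shared fixtures and independent oracles, rebuilt in code at test time.

# Global-mean parameter sets used by the synthetic lattice experiments:
# degradation consistent with the reporter half-life prior, equilibrium at
# 100 molecules, Type-II-like regulation for the limit-cycle truth and a
# provably damped Hill coefficient (|H'| < mu) for the damped truth.
lc_truth <- function(grid_step = 0.5) {
  mu <- exp(-0.55)
  oscillator_params(R = 2 * mu * 100, K = 100, n = 5.57, mu = mu,
                    kernel = delay_kernel_from_moments(9.4, 4.2,
                                                       grid_step = grid_step))
}

damped_truth <- function(grid_step = 0.5) {
  mu <- exp(-0.55)
  oscillator_params(R = 2 * mu * 100, K = 100, n = 1.5, mu = mu,
                    kernel = delay_kernel_from_moments(9.4, 4.2,
                                                       grid_step = grid_step))
}

# one synthetic single-location frame series from given params
synth_series <- function(params, seed, frames = 250, exposure = 0.5,
                         dt = 0.1) {
  e <- simulate_paths(set_kernel_step(params, dt), frames * exposure, dt,
                      seed = seed, init = "limit_cycle")
  simulate_observation(e, params, exposure, seed = seed + 1L)
}

# Independent naive full-matrix Kalman filter for the linear (n = 0)
# model, same discretization contract as the package filter but built
# from dense textbook matrix operations.
kalman_oracle_n0 <- function(y, R, mu, kappa, sigeta, dmean, dsd,
                             tau_max = 24, h = 0.5, r = 1L, diffuse = 10) {
  v <- clockfield:::cpp_state_weights(dmean^2 / dsd^2, dmean / dsd^2,
                                      tau_max, h)
  D <- length(v)
  xs <- R / (2 * mu)
  init <- if (y[1] > 0) y[1] / (kappa * r * h) else xs
  m <- rep(init, D)
  P <- diag(diffuse * xs, D)
  A <- rbind(c(1 - mu * h, rep(0, D - 1)), cbind(diag(1, D - 1), 0))
  cvec <- numeric(D)
  cvec[1:(r + 1)] <- kappa * h
  cvec[c(1, r + 1)] <- kappa * h / 2
  ll <- 0
  for (t in seq_along(y)) {
    for (s in seq_len(r)) {
      mnew <- as.numeric(A %*% m)
      mnew[1] <- m[1] + (R / 2 - mu * m[1]) * h
      Q <- matrix(0, D, D)
      Q[1, 1] <- max((R / 2 + mu * max(m[1], 0)) * h, 1e-12)
      P <- A %*% P %*% t(A) + Q
      m <- mnew
    }
    S <- as.numeric(t(cvec) %*% P %*% cvec) + sigeta^2
    innov <- y[t] - sum(cvec * m)
    ll <- ll + dnorm(innov, 0, sqrt(S), log = TRUE)
    Kg <- as.numeric(P %*% cvec) / S
    m <- m + Kg * innov
    P <- P - outer(Kg, as.numeric(P %*% cvec))
    diag(P)[diag(P) < 0] <- 0
  }
  ll
}

# Hayes-type criterion for the fixed (discrete) delay characteristic
# equation lambda + mu - H' exp(-lambda tau) = 0 with H' < 0: unstable
# iff |H'| > mu and tau > acos(-mu/|H'|) / sqrt(H'^2 - mu^2).
hayes_unstable <- function(hprime_abs, mu, tau) {
  if (hprime_abs <= mu) return(FALSE)
  tau > acos(-mu / hprime_abs) / sqrt(hprime_abs^2 - mu^2)
}

# minimal hand-built posterior_chain holding constant per-draw parameters
fake_chain <- function(theta_rows, mu = 0.25) {
  n <- nrow(theta_rows)
  structure(list(theta = theta_rows, mu = rep(mu, n),
                 kappa = rep(2.5e-3, n), sigma_eta = rep(0.07, n),
                 accept = matrix(TRUE, n, 1), n_iter = n, burn = 0L,
                 spatial = FALSE, L = 1L, tau_max = 24, h = 0.5,
                 exposure = 0.5), class = "posterior_chain")
}
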