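test_that("Hill repression has the textbook anchor points", {
  p <- reference_params("II")
  expect_equal(hill_rate(p$K, p), p$R / 2)          # midpoint
  expect_equal(hill_rate(0, p), p$R)                # maximal transcription
  expect_equal(hill_rate(100, p), 25)               # R = 50, K = 100
  expect_error(hill_rate(-1, p), "non-negative")
  # strictly decreasing for n > 0, constant for n = 0
  z <- seq(0, 400, by = 20)
  expect_true(all(diff(hill_rate(z, p)) < 0))
  p0 <- p; p0$n <- 0
  expect_true(all(hill_rate(z, p0) == p0$R / 2))
  expect_true(all(hill_derivative(z, p) <= 0))
})

test_that("equilibrium solves the balance equation uniquely", {
  p <- reference_params("II")
  expect_equal(equilibrium_state(p), 100, tolerance = 1e-9)  # R = 2 mu K
  p0 <- p; p0$n <- 0
  expect_equal(equilibrium_state(p0), p$R / (2 * p$mu), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    pp <- oscillator_params(R = runif(1, 5, 200), K = runif(1, 20, 300),
                            n = runif(1, 0, 8), mu = runif(1, 0.05, 1),
                            kernel = p$kernel)
    xs <- equilibrium_state(pp)
    expect_lt(abs(hill_rate(xs, pp) - pp$mu * xs), 1e-8 * pp$R)
  }
  # monotone in mu (decreasing) and R (increasing)
  eq <- function(R, mu) equilibrium_state(
    oscillator_params(R = R, K = 100, n = 4, mu = mu, kernel = p$kernel))
  expect_true(all(diff(sapply(c(0.1, 0.25, 0.5, 1), function(m)
    eq(50, m))) < 0))
  expect_true(all(diff(sapply(c(20, 50, 100, 200), function(R)
    eq(R, 0.25))) > 0))
})

test_that("CLE drift and diffusion balance at equilibrium", {
  p <- reference_params("II")
  xs <- equilibrium_state(p)
  dd <- cle_drift_diffusion(xs, xs, p)
  expect_equal(dd$drift, 0, tolerance = 1e-8)
  expect_equal(dd$diffusion_variance_rate, 2 * p$mu * xs, tolerance = 1e-8)
  dd0 <- cle_drift_diffusion(0, 0, p)
  expect_equal(dd0$drift, p$R)
  expect_equal(dd0$diffusion_variance_rate, p$R)
  # variance rate is drift + 2 mu x >= 0 everywhere
  for (x in c(0, 10, 500)) for (z in c(0, 50, 400)) {
    dd <- cle_drift_diffusion(x, z, p)
    expect_gte(dd$drift + p$mu * x, 0)
  }
  expect_error(cle_drift_diffusion(-1, 0, p), "non-negative")
})

test_that("macroscopic rate equation vanishes at equilibrium and pulls back", {
  p <- reference_params("II")
  xs <- equilibrium_state(p)
  expect_equal(macroscopic_rhs(function(t) rep(xs, length(t)), 0, p), 0,
               tolerance = 1e-8)
  expect_gt(macroscopic_rhs(function(t) rep(0.5 * xs, length(t)), 0, p), 0)
  expect_error(macroscopic_rhs(function(t) stop("short"), 0, p), "history")
})

test_that("deterministic integration relaxes to equilibrium for a damped set", {
  # n = 1, sd = 5: |H'| < mu, unconditionally stable
  mu <- 0.25
  p <- oscillator_params(R = 50, K = 100, n = 1, mu = mu,
                         kernel = delay_kernel_from_moments(9.4, 5,
                                                            grid_step = 0.1))
  xs <- equilibrium_state(p)
  e <- simulate_paths(p, 200, 0.1,
                      init = rep(1.2 * xs, 241), stochastic = FALSE)
  expect_lt(abs(e$paths[1, ncol(e$paths)] - xs), 1e-3 * xs)
  if (requireNamespace("deSolve", quietly = TRUE)) {
    # independent DDE oracle on the same problem
    k <- p$kernel
    rhs <- function(t, y, parms) {
      past <- vapply(k$midpoints, function(s)
        if (t - s <= 0) 1.2 * xs else deSolve::lagvalue(t - s), numeric(1))
      z <- sum(k$weights * past)
      list(hill_rate(z, p) - mu * y)
    }
    sol <- deSolve::dede(y = 1.2 * xs, times = seq(0, 200, by = 0.5),
                         func = rhs, parms = NULL)
    ours <- e$paths[1, match(sol[, 1], e$times)]
    expect_lt(max(abs(sol[, 2] - ours)) / xs, 0.02)
  }
})
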