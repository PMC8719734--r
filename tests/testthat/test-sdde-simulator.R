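test_that("simulation is seed-reproducible and equilibria are fixed points", {
  p <- set_kernel_step(reference_params("II"), 0.1)
  a <- simulate_paths(p, 24, 0.1, n_paths = 3, seed = 7)
  b <- simulate_paths(p, 24, 0.1, n_paths = 3, seed = 7)
  expect_identical(a$paths, b$paths)
  expect_error(simulate_paths(p, 24, 0.1), "seed")
  expect_error(simulate_paths(p, 24, 0.2), "grid step")
  # deterministic mode from constant equilibrium history stays there
  xs <- equilibrium_state(p)
  e <- simulate_paths(p, 48, 0.1, init = "equilibrium", stochastic = FALSE)
  expect_lt(max(abs(e$paths - xs)), 1e-6 * xs)
})

test_that("Type-I deterministic dynamics sustain a stable-amplitude cycle", {
  p <- set_kernel_step(reference_params("I"), 0.1)
  e <- simulate_paths(p, 144, 0.1, init = "limit_cycle", stochastic = FALSE)
  x <- e$paths[1, ]
  t <- e$times
  amp <- function(w) diff(range(x[t >= w[1] & t < w[2]]))
  a1 <- amp(c(24, 48)); a5 <- amp(c(120, 144))
  expect_gt(a5, 50)                        # sustained, large amplitude
  expect_lt(abs(a5 - a1) / a1, 0.02)       # stable over six days
})

test_that("halving the step barely moves the deterministic period", {
  per <- function(dt) {
    p <- set_kernel_step(reference_params("II"), dt)
    e <- simulate_paths(p, 144, dt, init = "limit_cycle",
                        stochastic = FALSE)
    median(diff(extract_peak_phases(e$paths[1, ], e$times, 24)))
  }
  expect_lt(abs(per(0.1) - per(0.05)) / per(0.1), 0.01)
})

test_that("with noise off and n = 0 the path solves the linear ODE", {
  mu <- 0.25
  p <- oscillator_params(R = 50, K = 100, n = 0, mu = mu,
                         kernel = delay_kernel_from_moments(9.4, 4.2,
                                                            grid_step = 0.1))
  x0 <- 10
  e <- simulate_paths(p, 24, 0.1, init = rep(x0, 241), stochastic = FALSE)
  exact <- p$R / (2 * mu) + (x0 - p$R / (2 * mu)) * exp(-mu * e$times)
  expect_lt(max(abs(e$paths[1, ] - exact)), 0.5)  # O(dt) Euler error
})

test_that("ensemble mean tracks the macroscopic solution at high copy number", {
  p <- reference_params("II")
  ph <- oscillator_params(R = 100 * p$R, K = 100 * p$K, n = p$n, mu = p$mu,
                          kernel = delay_kernel_from_moments(9.4, 4.2,
                                                             grid_step = 0.1))
  det <- simulate_paths(ph, 72, 0.1, init = "limit_cycle",
                        stochastic = FALSE)
  ens <- simulate_paths(ph, 72, 0.1, n_paths = 300,
                        init = det$history[1, ], seed = 99)
  mpath <- colMeans(ens$paths)
  expect_lt(max(abs(mpath - det$paths[1, ])) / mean(det$paths[1, ]), 0.05)
})

test_that("measurement model integrates, scales and adds frame noise", {
  p <- reference_params("II")
  pq <- p; pq$sigma_eta <- 0
  k01 <- set_kernel_step(p, 0.1)
  const <- simulate_paths(k01, 50, 0.1, init = rep(80, 241),
                          stochastic = FALSE)
  # constant path: every frame is kappa * c * exposure exactly
  const$paths[] <- 80
  rec <- simulate_observation(const, pq, 0.5)
  expect_equal(unname(rec$values[1, 1]), p$kappa * 80 * 0.5,
               tolerance = 1e-12)
  expect_lt(diff(range(rec$values)), 1e-12)
  expect_error(simulate_observation(const, p, 0.23), "multiple")
  # noise moments: sample variance around the exact frame value
  long <- const
  long$paths <- matrix(80, 1, 50001)
  long$times <- seq(0, by = 0.1, length.out = 50001)
  recn <- simulate_observation(long, p, 0.5, seed = 5)
  expect_equal(sd(recn$values), p$sigma_eta, tolerance = 0.03)
  # mean within ~4 standard errors of the noise-free frame value
  expect_lt(abs(mean(recn$values) - p$kappa * 80 * 0.5),
            4 * p$sigma_eta / sqrt(length(recn$values)))
})

test_that("rectangular perturbations inject the advertised mass", {
  mu <- 0.25
  p <- oscillator_params(R = 50, K = 100, n = 0, mu = mu,
                         kernel = delay_kernel_from_moments(9.4, 4.2,
                                                            grid_step = 0.1))
  base <- simulate_paths(p, 48, 0.1, init = "equilibrium",
                         stochastic = FALSE)
  pt <- perturbation(onset = 10, duration = 2, amplitude = 130)
  shocked <- simulate_paths(p, 48, 0.1, init = "equilibrium",
                            perturbation = pt, stochastic = FALSE)
  dx <- shocked$paths[1, ] - base$paths[1, ]
  t <- base$times
  i12 <- which.min(abs(t - 12))
  expect_lt(max(abs(dx[t < 10])), 1e-12)   # causal
  # linear response at end of window: (a/mu) (1 - exp(-mu d)), rate a = 130
  expect_equal(dx[i12], 130 / mu * (1 - exp(-mu * 2)), tolerance = 1)
  # "total" mode injects amplitude molecules regardless of duration
  pt2 <- perturbation(10, 2, 130, mode = "total")
  shocked2 <- simulate_paths(p, 48, 0.1, init = "equilibrium",
                             perturbation = pt2, stochastic = FALSE)
  dx2 <- shocked2$paths[1, ] - base$paths[1, ]
  expect_equal(dx2[i12], 65 / mu * (1 - exp(-mu * 2)), tolerance = 0.5)
})

test_that("synthetic lattice data carry coherent ground truth", {
  lc <- lc_truth()
  syn <- generate_synthetic_dataset(3, 4, lc,
                                    hyper_variances = c(R = 0.005,
                                                        K = 0.005,
                                                        n = 0.005,
                                                        dmean = 0.002,
                                                        dsd = 0.005),
                                    horizon = 60, seed = 31)
  expect_s3_class(syn$record, "luminescence_record")
  expect_equal(dim(syn$record$values), c(12, 120))
  expect_equal(colSums(syn$field$eps), rep(0, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # per-location parameters are theta * exp(eps)
  expect_equal(syn$location_params[, "R"], lc$R * exp(syn$field$eps[, "R"]),
               ignore_attr = TRUE)
  # near-degenerate hyper-variances collapse to shared parameters
  syn0 <- generate_synthetic_dataset(2, 2, lc,
                                     hyper_variances = rep(1e-10, 5),
                                     horizon = 30, seed = 32)
  expect_lt(diff(range(syn0$location_params[, "n"])), 1e-4)
  expect_error(generate_synthetic_dataset(2, 2, lc,
                                          hyper_variances = c(-1, 1, 1, 1, 1),
                                          horizon = 30, seed = 1),
               "positive")
})
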