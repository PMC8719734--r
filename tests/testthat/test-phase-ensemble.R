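test_that("peak extraction recovers cosine maxima", {
  t <- seq(0, 120, by = 0.1)
  x <- cos(2 * pi * t / 24)
  pk <- extract_peak_phases(x, t, expected_period = 24)
  expect_equal(pk, seq(0, 120, by = 24)[-1][seq_along(pk)],
               tolerance = 0.05, ignore_attr = TRUE)
  # robust to moderate white noise (SNR 10)
  set.seed(5)
  err <- replicate(20, {
    xn <- x + rnorm(length(t), 0, sqrt(0.5 / 10))
    pkn <- extract_peak_phases(xn, t, 24)
    mean(abs(pkn[1:4] - pk[1:4]))
  })
  expect_lt(median(err), 0.5)
  expect_error(extract_peak_phases(x[t <= 30], t[t <= 30], 24),
               "two expected periods")
})

test_that("deterministic limit-cycle peaks are nearly equally spaced", {
  p <- set_kernel_step(reference_params("I"), 0.1)
  e <- simulate_paths(p, 168, 0.1, init = "limit_cycle", stochastic = FALSE)
  gaps <- diff(extract_peak_phases(e$paths[1, ], e$times, 24))
  expect_lt(sd(gaps) / mean(gaps), 0.02)
})

test_that("circular statistics behave on known configurations", {
  expect_equal(circ_R(rep(0.7, 50)), 1)
  expect_equal(circ_mean(rep(0.7, 50)), 0.7)
  expect_lt(circ_R(runif(5000, -pi, pi)), 0.05)
  expect_equal(circ_mean(c(-0.1, 0.1)), 0, tolerance = 1e-12)
  # wrapping is 2*pi-periodic into (-pi, pi]
  expect_equal(clockfield:::.wrap(2 * pi + 0.3), 0.3, tolerance = 1e-12)
  expect_equal(clockfield:::.wrap(-2 * pi - 0.3), -0.3, tolerance = 1e-12)
})

test_that("matched ensembles agree outside the perturbation's causal cone", {
  p <- set_kernel_step(reference_params("I"), 0.1)
  det <- simulate_paths(p, 48, 0.1, init = "limit_cycle",
                        stochastic = FALSE)
  pt <- perturbation(onset = 30, duration = 1, amplitude = 130)
  a <- simulate_paths(p, 48, 0.1, n_paths = 5, init = det$history[1, ],
                      seed = 8)
  b <- simulate_paths(p, 48, 0.1, n_paths = 5, init = det$history[1, ],
                      perturbation = pt, seed = 8)
  pre <- a$times < 30
  expect_identical(a$paths[, pre], b$paths[, pre])
  expect_gt(max(abs(a$paths[, !pre] - b$paths[, !pre])), 1)
})

test_that("an unshocked ensemble stays synchronized with no mean shift", {
  ps <- perturbation_study(reference_params("I"),
                           perturbation(0, 1, 0), n_paths = 60,
                           horizon = 144, seed = 13)
  expect_s3_class(ps, "phase_distribution")
  expect_lt(abs(ps$circular_mean_shift), 0.15)
  expect_gt(ps$synchrony, 0.8)
  expect_true(all(abs(ps$phase_shifts) <= pi, na.rm = TRUE))
  expect_error(perturbation_study(reference_params("I"),
                                  perturbation(0, 1, 0), n_paths = 10,
                                  horizon = 60, seed = 1), "too short")
})

test_that("a trough-anchored shock disperses the ensemble and delays it", {
  shock <- perturbation(0, 1, 130)
  ref <- perturbation_study(reference_params("II"), perturbation(0, 1, 0),
                            n_paths = 60, horizon = 144, seed = 19)
  hit <- perturbation_study(reference_params("II"), shock,
                            n_paths = 60, horizon = 144, seed = 19)
  expect_lt(hit$synchrony, ref$synchrony)
  # raising mRNA at the trough moves the trajectory toward its peak
  # state, so the subsequent cycles arrive late (a phase delay)
  expect_lt(hit$circular_mean_shift, 0)
  # a gentler shock of the same duration perturbs the phase less
  soft <- perturbation_study(reference_params("II"),
                             perturbation(0, 1, 30),
                             n_paths = 60, horizon = 144, seed = 19)
  expect_lt(abs(soft$circular_mean_shift), abs(hit$circular_mean_shift))
})
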