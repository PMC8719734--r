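test_that("linear-model filter equals the dense Kalman oracle", {
  set.seed(3)
  for (i in 1:15) {
    R <- runif(1, 20, 80); mu <- runif(1, 0.1, 0.6)
    dmean <- runif(1, 5, 12); dsd <- runif(1, 1, 5)
    kappa <- 2.5e-3; sig <- runif(1, 0.02, 0.1)
    y <- abs(rnorm(120, kappa * 0.5 * R / (2 * mu), 0.03))
    p <- oscillator_params(R = R, K = 100, n = 0, mu = mu,
                           kernel = delay_kernel_from_moments(dmean, dsd),
                           kappa = kappa, sigma_eta = sig)
    a <- filter_loglik(y, p, exposure = 0.5)
    b <- kalman_oracle_n0(y, R, mu, kappa, sig, dmean, dsd)
    expect_lt(abs(a$loglik - b) / abs(b), 1e-8)
  }
})

test_that("huge measurement noise disables the Kalman gain", {
  p <- lc_truth()
  rec <- synth_series(p, seed = 61, frames = 120)
  y1 <- rec$values[1, ]
  # second series: same first frame (same initialization), fresh noise
  rec2 <- synth_series(p, seed = 62, frames = 120)
  y2 <- c(y1[1], rec2$values[1, -1])
  pn <- p; pn$sigma_eta <- 1e3
  a <- filter_loglik(y1, pn, exposure = 0.5)
  b <- filter_loglik(y2, pn, exposure = 0.5)
  # with gain ~ 0 the predictions are pure prior propagation and ignore
  # the observations entirely
  expect_lt(max(abs(a$pred_mean - b$pred_mean)) / max(abs(a$pred_mean)),
            1e-4)
  # the predictive SD is the read noise itself
  expect_true(all(abs(a$pred_sd - 1e3) / 1e3 < 1e-4))
  # so the likelihood is the iid Gaussian score of y around the prior
  # predictive mean path
  expect_equal(a$loglik, sum(dnorm(y1, a$pred_mean, 1e3, log = TRUE)),
               tolerance = 1e-6)
})

test_that("likelihood prefers the generating parameters", {
  p <- lc_truth()
  wrong <- p; wrong$R <- 2 * p$R
  d <- vapply(1:12, function(i) {
    rec <- synth_series(p, seed = 300 + i, frames = 150)
    y <- rec$values[1, ]
    filter_loglik(y, p, 0.5)$loglik - filter_loglik(y, wrong, 0.5)$loglik
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("initial state inverts the measurement equation with fallback", {
  p <- lc_truth()
  st <- init_filter_state(p$kappa * 77 * 0.5, p, h = 0.5)
  expect_equal(st$mean[1], 77, tolerance = 1e-12)
  expect_equal(length(st$mean), 49)
  st0 <- init_filter_state(-0.2, p, h = 0.5)
  expect_equal(st0$mean[1], equilibrium_state(p), tolerance = 1e-9)
  expect_equal(st$log_likelihood_accum, 0)
  expect_true(all(diag(st$covariance) == 10 * equilibrium_state(p)))
})

test_that("the likelihood is insensitive to the diffuse initialization", {
  p <- lc_truth()
  rec <- synth_series(p, seed = 71, frames = 250)
  y <- rec$values[1, ]
  l5 <- filter_loglik(y, p, 0.5, diffuse = 5)$loglik
  l20 <- filter_loglik(y, p, 0.5, diffuse = 20)$loglik
  # a factor-4 change in the diffuse prior moves 250 frames of
  # log-likelihood by a few nats at most (the transient dies within the
  # first cycle)
  expect_lt(abs(l5 - l20), 3)
})

test_that("coarse profile search lands near the generating parameters", {
  p <- lc_truth()
  rec <- synth_series(p, seed = 81, frames = 500)
  y <- rec$values[1, ]
  ll <- function(R, n, dmean) {
    pp <- oscillator_params(R = R, K = p$K, n = n, mu = p$mu,
                            kernel = delay_kernel_from_moments(
                              dmean, kernel_sd(p$kernel)),
                            kappa = p$kappa, sigma_eta = p$sigma_eta)
    filter_loglik(y, pp, 0.5)$loglik
  }
  Rg <- p$R * seq(0.6, 1.4, by = 0.1)
  ng <- p$n * seq(0.6, 1.4, by = 0.1)
  dg <- 9.4 * seq(0.6, 1.4, by = 0.1)
  bR <- Rg[which.max(vapply(Rg, function(R) ll(R, p$n, 9.4), numeric(1)))]
  bn <- ng[which.max(vapply(ng, function(n) ll(p$R, n, 9.4), numeric(1)))]
  bd <- dg[which.max(vapply(dg, function(d) ll(p$R, p$n, d), numeric(1)))]
  expect_lt(abs(bR - p$R) / p$R, 0.15)
  expect_lt(abs(bn - p$n) / p$n, 0.15)
  expect_lt(abs(bd - 9.4) / 9.4, 0.15)
})

test_that("degenerate inputs are flagged", {
  p <- lc_truth()
  expect_error(filter_loglik(0.1, p, 0.5), "2 frames")
  expect_error(filter_loglik(c(0.1, 0.2), p, 0.5, h = 0.3), "divide")
  bad <- p
  bad$kernel <- delay_kernel_from_moments(9, 2, grid_step = 0.25)
  expect_error(filter_loglik(c(0.1, 0.2), bad, 0.5), "grid step")
})
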