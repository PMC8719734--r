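test_that("block aggregation sums tiles and conserves intensity", {
  fr <- array(1, c(3, 8, 8))
  st <- image_stack(fr, 0.5)
  rec <- aggregate_blocks(st, 4)
  expect_equal(dim(rec$values), c(4, 3))
  expect_true(all(rec$values == 16))
  expect_equal(sum(rec$values[, 1]), sum(fr[1, , ]))
  # block 1 is the identity (locations = pixels)
  rec1 <- aggregate_blocks(st, 1)
  expect_equal(dim(rec1$values), c(64, 3))
  expect_true(all(rec1$values == 1))
  # uneven dimensions drop the remainder with a warning
  st2 <- image_stack(array(1, c(2, 9, 10)), 0.5)
  expect_warning(rec2 <- aggregate_blocks(st2, 4), "dropped")
  expect_equal(rec2$rows * rec2$cols, 2 * 2)
})

test_that("alternate subsampling keeps the even-index sublattice", {
  vals <- matrix(seq_len(16 * 3), 16, 3)
  rec <- luminescence_record(vals, 0.5, rows = 4, cols = 4)
  sub <- subsample_alternate(rec)
  expect_equal(sub$rows, 2); expect_equal(sub$cols, 2)
  # kept locations: lattice rows 1,3 and columns 1,3 (row-major order)
  expect_equal(sub$values[, 1], vals[c(1, 3, 9, 11), 1])
  # repeated halving, not idempotence
  sub2 <- subsample_alternate(subsample_alternate(
    luminescence_record(matrix(1, 64, 2), 0.5, rows = 8, cols = 8)))
  expect_equal(sub2$rows, 2)
})

test_that("linear detrending removes a ramp and keeps the level", {
  t <- 1:100
  y <- rbind(5 - 0.03 * t, 2 + 0.01 * t)
  rec <- luminescence_record(y, 0.5)
  out <- detrend_linear(rec)
  expect_equal(out$slope, c(-0.03, 0.01), tolerance = 1e-12)
  expect_lt(diff(range(out$record$values[1, ])), 1e-10)   # flat
  expect_equal(rowMeans(out$record$values), rowMeans(y), tolerance = 1e-12)
  # idempotent
  out2 <- detrend_linear(out$record)
  expect_lt(max(abs(out2$record$values - out$record$values)), 1e-10)
})

test_that("channel-difference estimator isolates the read noise", {
  sig <- sin(seq(0, 20, length.out = 2000))
  expect_equal(estimate_noise_variance(sig, sig), 0)
  set.seed(3)
  a <- sig + rnorm(2000, 0, 2); b <- sig + rnorm(2000, 0, 2)
  expect_equal(estimate_noise_variance(a, b), 4, tolerance = 0.3)
  # invariant to any shared signal
  shift <- rnorm(2000)
  expect_equal(estimate_noise_variance(a + shift, b + shift),
               estimate_noise_variance(a, b), tolerance = 1e-10)
  # bias factor (T-1)/T at small T
  est <- replicate(4000, {
    d1 <- rnorm(5, 0, 1); d2 <- rnorm(5, 0, 1)
    estimate_noise_variance(d1, d2)
  })
  expect_equal(mean(est), (5 - 1) / 5, tolerance = 0.03)
  expect_error(estimate_noise_variance(1:3, 1:4), "equal length")
})

test_that("noise-prior fitting moment-matches on the log scale", {
  expect_error(fit_noise_prior(rep(0.01, 5)), "at least 10")
  fp <- fit_noise_prior(rep(0.01, 12))
  expect_equal(fp$log_mean, log(0.01))
  expect_equal(fp$log_sd, 0)
  set.seed(11)
  est <- exp(rnorm(500, -5.3, 0.17))
  fp2 <- fit_noise_prior(est)
  expect_equal(fp2$log_mean, -5.3, tolerance = 0.05)
  expect_equal(fp2$log_sd, 0.17, tolerance = 0.03)
  expect_warning(fit_noise_prior(c(est, -1)), "dropped")
  # plugs into the prior spec on the same scale
  pr <- default_priors(fp2$log_mean, fp2$log_sd)
  expect_equal(pr$logsig2$mean, fp2$log_mean)
})

test_that("residual diagnostics accept a well-specified fit and find
           injected periodicity", {
  p <- lc_truth()
  par_row <- c(p$R, p$K, p$n, p$mu, 9.4, 4.2, p$kappa, p$sigma_eta)
  set.seed(55)
  recs <- lapply(1:4, function(i) synth_series(p, seed = 500 + i,
                                               frames = 200))
  Y <- do.call(rbind, lapply(recs, function(r) r$values[1, ]))
  rec <- luminescence_record(Y, 0.5)
  rep1 <- residual_diagnostics(rec, par_row, B = 200)
  expect_true(all(rep1$ks$decision == "accept"))
  # inject a strong 12-hour sinusoid into the observations
  t <- (1:200) * 0.5
  Y12 <- sweep(Y, 2, 0.12 * sin(2 * pi * t / 12), `+`)
  rep2 <- residual_diagnostics(luminescence_record(Y12, 0.5), par_row,
                               B = 200)
  found <- unlist(rep2$periods)
  expect_true(any(abs(found - 12) < 1.5))
  # grossly non-Gaussian residuals are rejected
  Yc <- Y; Yc[1, ] <- rep(c(0.05, 0.4), 100)
  rep3 <- residual_diagnostics(luminescence_record(Yc, 0.5), par_row,
                               B = 50)
  expect_equal(rep3$ks$decision[1], "reject")
})

test_that("records and lattice maps round-trip through CSV", {
  vals <- matrix(rnorm(12), 4, 3)
  rec <- luminescence_record(vals, 0.5, rows = 2, cols = 2)
  path <- tempfile(fileext = ".csv")
  write_record_csv(rec, path)
  back <- read_record_csv(path)
  expect_equal(back$values, vals, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$exposure, 0.5)
  expect_equal(c(back$rows, back$cols), c(2, 2))
  lat <- tempfile(fileext = ".csv")
  write_lattice_csv(1:4, 2, 2, lat)
  m <- as.matrix(read.csv(lat))
  expect_equal(m[1, ], c(1, 2), ignore_attr = TRUE)
  unlink(c(path, paste0(path, ".meta"), lat))
})
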