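# Imaging-data preprocessing, measurement-noise estimation and residual
# diagnostics.

#' Image stack container
#'
#' @param frames Numeric array `n_frames x height x width` of
#'   non-negative intensities.
#' @param frame_interval Hours between frame starts (the exposure).
#' @export
image_stack <- function(frames, frame_interval) {
  if (length(dim(frames)) != 3L || dim(frames)[1] < 2L)
    .invalid("'frames' must be an n_frames x height x width array (>= 2 frames)")
  if (any(frames < 0)) .invalid("intensities must be non-negative")
  .check_scalar(frame_interval, "frame_interval")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "image_stack")
}

#' Read a multi-frame grayscale TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param frame_interval Hours between frames.
#' @export
read_image_stack <- function(path, frame_interval) {
  if (!requireNamespace("tiff", quietly = TRUE))
    .invalid("the 'tiff' package is required to read TIFF stacks")
  fr <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  frames <- array(0, c(length(fr), nrow(fr[[1]]), ncol(fr[[1]])))
  for (i in seq_along(fr)) frames[i, , ] <- fr[[i]]
  image_stack(frames, frame_interval)
}

#' Aggregate pixels into square block locations
#'
#' Sums each `block x block` pixel tile per frame (a location roughly the
#' size of a quarter neuron at default `block = 4`), raising the
#' signal-to-noise ratio towards the single-cell level.  Trailing pixels
#' that do not fill a block are dropped with a warning.
#'
#' @param stack An [image_stack()].
#' @param block Block side in pixels.
#' @return A [luminescence_record()] with lattice layout.
#' @export
aggregate_blocks <- function(stack, block = 4L) {
  if (block <= 0) .invalid("'block' must be positive")
  d <- dim(stack$frames)
  nr <- d[2] %/% block; nc <- d[3] %/% block
  if (nr * block != d[2] || nc * block != d[3])
    warning("trailing pixels dropped: frame dimensions not divisible by block")
  if (nr < 1L || nc < 1L) .invalid("frames smaller than one block")
  vals <- matrix(0, nr * nc, d[1])
  for (f in seq_len(d[1])) {
    fr <- stack$frames[f, seq_len(nr * block), seq_len(nc * block),
                       drop = FALSE]
    dim(fr) <- c(nr * block, nc * block)
    # sum within block rows, then block columns
    a <- rowsum(fr, rep(seq_len(nr), each = block))
    b <- t(rowsum(t(a), rep(seq_len(nc), each = block)))
    vals[, f] <- as.numeric(t(b))   # row-major location order
  }
  luminescence_record(vals, stack$frame_interval, rows = nr, cols = nc)
}

#' Subsample alternate rows and columns of locations
#'
#' Keeps every other row and column of the location lattice (the first,
#' third, ... of each), quartering the computational cost of inference;
#' the adjacency implied by the layout is rebuilt on the subsampled
#' lattice.  Repeated application keeps halving the lattice (it is not
#' idempotent by design).
#'
#' @param record A [luminescence_record()] with lattice layout.
#' @return The subsampled record.
#' @export
subsample_alternate <- function(record) {
  if (is.na(record$rows) || record$rows < 2L || record$cols < 2L)
    .invalid("record must carry a lattice layout of at least 2 x 2")
  keep_r <- seq(1L, record$rows, by = 2L)
  keep_c <- seq(1L, record$cols, by = 2L)
  loc <- as.vector(outer(keep_c, (keep_r - 1L) * record$cols, `+`))
  loc <- sort(loc)
  luminescence_record(record$values[loc, , drop = FALSE], record$exposure,
                      rows = length(keep_r), cols = length(keep_c))
}

#' Remove a per-location linear trend
#'
#' Subtracts an ordinary least squares line over the frame index from
#' each location's series (substrate consumption produces a decreasing
#' trend in bioluminescence recordings) while re-adding the series mean,
#' so the detrended signal keeps its original level and the light-scaling
#' interpretation of the measurement model.
#'
#' @param record A [luminescence_record()].
#' @return List with `record` (detrended), `slope` and `intercept` per
#'   location (slope per frame interval).
#' @export
detrend_linear <- function(record) {
  Y <- record$values
  T <- ncol(Y)
  if (T < 3L) .invalid("need at least 3 frames to detrend")
  t <- seq_len(T)
  tc <- t - mean(t)
  denom <- sum(tc^2)
  slope <- as.numeric(Y %*% tc) / denom
  ybar <- rowMeans(Y)
  detr <- Y - outer(slope, tc)
  rec <- record; rec$values <- detr
  list(record = rec, slope = slope, intercept = ybar - slope * mean(t))
}

#' Two-channel maximum-likelihood noise variance estimator
#'
#' When two simultaneously recorded channels contain the same underlying
#' signal corrupted by independent stationary Gaussian read noise, the ML
#' estimator of the per-channel noise variance is
#' `(1/(2T)) * sum((d_t - mean(d))^2)` with `d = channel_a - channel_b`.
#' It is invariant to any shared signal and has expectation
#' `sigma^2 (T-1)/T`.
#'
#' @param channel_a,channel_b Equal-length numeric series.
#' @return Variance estimate.
#' @export
estimate_noise_variance <- function(channel_a, channel_b) {
  if (length(channel_a) != length(channel_b))
    .invalid("channels must have equal length")
  T <- length(channel_a)
  if (T < 2L) .invalid("need at least 2 frames")
  d <- channel_a - channel_b
  sum((d - mean(d))^2) / (2 * T)
}

#' Fit a lognormal prior to per-location noise variance estimates
#'
#' Gaussian moment matching on the log variance estimates; the result
#' plugs directly into [default_priors()] as the log noise-variance
#' prior.  Non-positive estimates are dropped with a warning.
#'
#' @param estimates Per-location variance estimates (at least 10
#'   positive).
#' @return List with `log_mean` and `log_sd`.
#' @export
fit_noise_prior <- function(estimates) {
  bad <- !is.finite(estimates) | estimates <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive noise estimates dropped")
    estimates <- estimates[!bad]
  }
  if (length(estimates) < 10L)
    .invalid("need at least 10 positive estimates")
  l <- log(estimates)
  s <- sqrt(mean((l - mean(l))^2))
  list(log_mean = mean(l), log_sd = s)
}

#' Residual diagnostics of the fitted state-space model
#'
#' One-step-ahead standardized filter residuals per location are tested
#' for Gaussianity (Kolmogorov-Smirnov against the standard normal, with
#' Bonferroni correction at family level `alpha`) and for remaining
#' periodicity by a periodogram bootstrap: residuals are resampled with
#' replacement `B` times and observed periodogram peaks in the 1-30 h
#' band exceeding the bootstrap 99% envelope are retained.
#'
#' @param record A [luminescence_record()].
#' @param par_matrix Per-location parameter matrix with columns
#'   `R, K, n, mu, dmean, dsd, kappa, sigma_eta` (one row recycles).
#' @param alpha Family-wise level of the KS test.
#' @param B Bootstrap replicates.
#' @param h Filter substep (defaults to the exposure).
#' @param tau_max Delay truncation bound, hours.
#' @return An object of class `residual_report`: data frame `ks` with
#'   statistic, p-value and Bonferroni decision per location, and list
#'   `periods` of detected residual periods (hours) per location.
#' @export
residual_diagnostics <- function(record, par_matrix, alpha = 0.05, B = 500L,
                                 h = record$exposure, tau_max = 24) {
  Y <- record$values
  L <- nrow(Y)
  par_matrix <- matrix(as.numeric(par_matrix), ncol = 8L)
  par_matrix <- par_matrix[rep(seq_len(nrow(par_matrix)), length.out = L), ,
                           drop = FALSE]
  r <- as.integer(round(record$exposure / h))
  ks_stat <- ks_p <- numeric(L)
  periods <- vector("list", L)
  for (i in seq_len(L)) {
    f <- cpp_filter(Y[i, ], par_matrix[i, 1], par_matrix[i, 2],
                    par_matrix[i, 3], par_matrix[i, 4], par_matrix[i, 7],
                    par_matrix[i, 8], par_matrix[i, 5], par_matrix[i, 6],
                    tau_max, h, r, 10)
    if (!f$ok) .invalid("filter failed for location ", i)
    res <- (Y[i, ] - f$pred_mean) / f$pred_sd
    kt <- suppressWarnings(ks.test(res, "pnorm"))
    ks_stat[i] <- unname(kt$statistic)
    ks_p[i] <- kt$p.value
    periods[[i]] <- .residual_periods(res, record$exposure, B)
  }
  structure(list(
    ks = data.frame(location = seq_len(L), statistic = ks_stat,
                    p_value = ks_p,
                    decision = ifelse(ks_p < alpha / L, "reject", "accept")),
    periods = periods, alpha = alpha), class = "residual_report")
}

# periodogram peaks in the 1-30 h band exceeding the bootstrap 99%
# envelope under resampling with replacement (which destroys serial
# structure while preserving the marginal distribution)
.residual_periods <- function(res, exposure, B) {
  n <- length(res)
  pgram <- function(x) Mod(fft(x - mean(x)))[2:(n %/% 2)]^2 / n
  per <- n * exposure / seq_len(n %/% 2 - 1L)
  band <- per >= 1 & per <= 30
  obs <- pgram(res)
  env <- matrix(0, B, sum(band))
  for (b in seq_len(B)) env[b, ] <- pgram(sample(res, replace = TRUE))[band]
  thr <- apply(env, 2L, quantile, 0.99)
  hit <- which(obs[band] > thr)
  if (length(hit) == 0L) return(numeric(0))
  # local maxima among exceedances
  pb <- per[band]
  ob <- obs[band]
  hit[order(ob[hit], decreasing = TRUE)]
  pb[hit]
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("Residual diagnostics: %d location(s), %d KS rejection(s)\n",
              nrow(x$ks), sum(x$ks$decision == "reject")))
  invisible(x)
}
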