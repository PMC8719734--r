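# Blocked adaptive random-walk Metropolis over the hierarchical posterior:
# hyper-variances, global means, per-parameter CAR random effects,
# degradation rate, light scaling and measurement noise SD.

#' Default prior specification
#'
#' Vague zero-mean Gaussians with variance 100 for the logarithms of `R`,
#' `K` and `n`; uniform on `[0, 24]` and `[0, 20]` hours for the delay
#' mean and SD; an informative Gaussian on the log degradation rate with
#' mean -0.55 and SD 0.25 (elicited from reporter-protein half-life);
#' vague Gaussian on `log kappa`; a Gaussian on the log noise variance
#' whose defaults come from the two-channel noise estimator fitted to
#' imaging data (see [fit_noise_prior()]); and zero-mean Gaussians with
#' variance 25 on the log CAR hyper-variances.
#'
#' @param sigma_eta_log_mean,sigma_eta_log_sd Gaussian hyperparameters of
#'   the log noise-variance prior.
#' @return An object of class `prior_spec`.
#' @export
default_priors <- function(sigma_eta_log_mean = -5.3,
                           sigma_eta_log_sd = 0.17) {
  structure(list(
    logR = list(mean = 0, sd = 10),
    logK = list(mean = 0, sd = 10),
    logn = list(mean = 0, sd = 10),
    dmean = list(lower = 0, upper = 24),
    dsd = list(lower = 0, upper = 20),
    logmu = list(mean = -0.55, sd = 0.25),
    logkappa = list(mean = 0, sd = 10),
    logsig2 = list(mean = sigma_eta_log_mean, sd = sigma_eta_log_sd),
    logtau = list(mean = 0, sd = 5)
  ), class = "prior_spec")
}

# log prior of the transformed global-mean vector
# psi = (log R, log K, log n, delay mean, delay sd)
.lp_theta <- function(psi, pr) {
  if (psi[4] <= pr$dmean$lower || psi[4] >= pr$dmean$upper) return(-Inf)
  if (psi[5] <= pr$dsd$lower || psi[5] >= pr$dsd$upper) return(-Inf)
  dnorm(psi[1], pr$logR$mean, pr$logR$sd, log = TRUE) +
    dnorm(psi[2], pr$logK$mean, pr$logK$sd, log = TRUE) +
    dnorm(psi[3], pr$logn$mean, pr$logn$sd, log = TRUE)
}

#' Diminishing multiplicative scale adaptation
#'
#' One step of the acceptance-rate controller used for every proposal
#' block: the scale grows by the factor `1 + c` when the observed
#' acceptance rate is above target and shrinks by `1 - c` when below, and
#' the adaptation coefficient decays as `c <- c - c/1e4` so that
#' adaptation diminishes over the run (starting value 0.02).
#'
#' @param gamma Positive proposal scale.
#' @param c Adaptation coefficient in (0, 1).
#' @param observed_rate,target_rate Acceptance rates in `[0, 1]`.
#' @return List with the new `gamma` and `c`.
#' @export
adapt_scale <- function(gamma, c, observed_rate, target_rate) {
  .check_scalar(gamma, "gamma")
  if (!is.numeric(c) || c <= 0 || c >= 1) .invalid("'c' must be in (0, 1)")
  gamma <- if (observed_rate > target_rate) gamma * (1 + c)
           else gamma * (1 - c)
  list(gamma = gamma, c = c - c / 1e4)
}

#' Batch-means effective sample size
#'
#' `n * s^2 / T` where `T` is the batch-means estimate of the long-run
#' variance with batch size `floor(sqrt(n))`; the lugsail correction
#' (default) combines two batch sizes, `T = 2 T_b - T_{b/3}`, to offset
#' the downward bias of plain batch means under strong autocorrelation.
#' The estimate is clamped to `[0, n]`.
#'
#' @param chain Numeric vector of at least 100 draws.
#' @param lugsail Apply the lugsail correction?
#' @return Effective sample size (scalar).
#' @export
effective_sample_size <- function(chain, lugsail = TRUE) {
  n <- length(chain)
  if (n < 100L) .invalid("chain must have at least 100 draws")
  s2 <- var(chain)
  if (s2 == 0) {
    warning("constant chain; effective sample size is 0")
    return(0)
  }
  bmvar <- function(b) {
    a <- n %/% b
    mb <- colMeans(matrix(chain[seq_len(a * b)], b, a))
    b * sum((mb - mean(mb))^2) / (a - 1)
  }
  b <- max(2L, as.integer(floor(sqrt(n))))
  Tb <- bmvar(b)
  Tl <- if (lugsail) 2 * Tb - bmvar(max(1L, b %/% 3L)) else Tb
  if (!is.finite(Tl) || Tl <= 0) Tl <- Tb
  min(n, max(0, n * s2 / Tl))
}

# spectral heuristics for chain initialization: dominant circadian period
# -> delay mean; signal level -> R and K; field-typical kappa
.init_heuristics <- function(Y, exposure, priors, tau_max) {
  ybar <- colMeans(Y)
  ybar <- ybar - mean(ybar)
  n <- length(ybar)
  pw <- Mod(fft(ybar))[2:(n %/% 2)]^2
  per <- n * exposure / seq_len(n %/% 2 - 1L)   # hours per cycle
  band <- per >= 16 & per <= 32
  period <- if (any(band)) per[band][which.max(pw[band])] else 24
  dmean0 <- min(max(0.4 * period, 4), 0.6 * tau_max)
  kappa0 <- 2.5e-3
  mu0 <- exp(priors$logmu$mean)
  xbar <- max(mean(Y), 1e-6) / (kappa0 * exposure)
  list(psi = c(log(2 * mu0 * xbar), log(xbar), log(4),
               dmean0, 0.35 * dmean0),
       lmu = log(mu0), lkap = log(kappa0),
       lsig = priors$logsig2$mean / 2)
}

# per-location 8-column parameter matrix (R, K, n, mu, dmean, dsd, kappa,
# sigma_eta); eps may be NULL for a single location
.build_par <- function(psi, eps, lmu, lkap, lsig, L) {
  th <- c(exp(psi[1:3]), psi[4], psi[5])
  if (is.null(eps)) {
    loc <- matrix(th, 1L, 5L)
  } else {
    loc <- sweep(exp(eps), 2L, th, `*`)
  }
  # column order required by the filter: R, K, n, mu, dmean, dsd, kappa,
  # sigma_eta
  cbind(loc[, 1:3, drop = FALSE], exp(lmu), loc[, 4:5, drop = FALSE],
        exp(lkap), exp(lsig))[rep(seq_len(nrow(loc)), length.out = L), ,
                              drop = FALSE]
}

#' Fit the hierarchical oscillator model by blocked adaptive MCMC
#'
#' Fixed-scan sweep over the parameter blocks: CAR hyper-variances `tau`
#' (5-dimensional joint), global means `theta` (5-dimensional joint), the
#' five per-parameter random-effect fields (each `L`-dimensional with a
#' spherical Gaussian proposal, re-centred to sum to zero), and the
#' scalar degradation rate `mu`, light scaling `kappa` and noise SD
#' `sigma_eta`.  Multivariate blocks use an empirical-covariance proposal
#' scaled by an adaptive coefficient targeting acceptance 0.234;
#' 1-dimensional blocks target 0.45.  Scales follow the diminishing
#' multiplicative adaptation of [adapt_scale()], driven by windowed
#' acceptance rates.  Proposals implying a delay mean at or above
#' `tau_max`, or a non-finite filtering likelihood, are rejected.  The
#' first half of the output is treated as burn-in by downstream
#' summaries.
#'
#' @param data A [luminescence_record()] (one row per location).  A
#'   single-row record fits the non-spatial single-cell model (no
#'   random-effect or hyper-variance blocks).
#' @param priors A [default_priors()] specification.
#' @param n_iter Number of iterations (at least 2000 so that adaptation
#'   can stabilize).
#' @param seed Integer RNG seed.
#' @param init Optional named list overriding the spectral-heuristic
#'   initialization (`theta` as named vector `R,K,n,dmean,dsd`, scalars
#'   `mu`, `kappa`, `sigma_eta`, `tau`).
#' @param h Filter substep in hours; defaults to the exposure.
#' @param tau_max Delay truncation bound in hours.
#' @param diffuse Initial filter covariance factor.
#' @param control List of tuning knobs: `window` (acceptance window,
#'   default 100), `adapt_cov_every` (empirical covariance refresh,
#'   default 250), `c1` (initial adaptation coefficient, 0.02),
#'   `verbose`.
#' @return An object of class `posterior_chain`; see
#'   [posterior_summary()], [accept_rate()], [robustness_estimate()].
#' @export
run_mcmc <- function(data, priors = default_priors(), n_iter = 5000L,
                     seed, init = NULL, h = data$exposure, tau_max = 24,
                     diffuse = 10, control = list()) {
  stopifnot(inherits(data, "luminescence_record"))
  if (missing(seed)) .invalid("a 'seed' is required")
  if (n_iter < 2000L)
    .invalid("'n_iter' must be at least 2000 for adaptation to stabilize")
  ctl <- modifyList(list(window = 50L, adapt_cov_every = 250L, c1 = 0.02,
                         verbose = FALSE), control)
  Y <- data$values
  L <- nrow(Y)
  r <- data$exposure / h
  if (abs(r - round(r)) > 1e-8) .invalid("'h' must divide the exposure")
  r <- as.integer(round(r))
  spatial <- L > 1L
  if (spatial && (is.na(data$rows) || data$rows * data$cols != L))
    .invalid("spatial data needs a valid lattice layout (rows x cols)")
  W <- if (spatial) build_adjacency(data$rows, data$cols) else NULL
  Qlap <- if (spatial) diag(colSums(W)) - W else NULL
  set.seed(seed)

  ini <- .init_heuristics(Y, data$exposure, priors, tau_max)
  psi <- ini$psi; lmu <- ini$lmu; lkap <- ini$lkap; lsig <- ini$lsig
  if (!is.null(init$theta))
    psi <- c(log(init$theta[1:3]), init$theta[4], init$theta[5])
  if (!is.null(init$mu)) lmu <- log(init$mu)
  if (!is.null(init$kappa)) lkap <- log(init$kappa)
  if (!is.null(init$sigma_eta)) lsig <- log(init$sigma_eta)
  eps <- if (spatial) matrix(0, L, 5L) else NULL
  ltau <- if (spatial) {
    if (!is.null(init$tau)) log(rep(init$tau, length.out = 5L))
    else rep(log(0.01), 5L)
  } else NULL

  loglik <- function(par) cpp_filter_multi(Y, par, tau_max, h, r, diffuse)
  par <- .build_par(psi, eps, lmu, lkap, lsig, L)
  ll <- loglik(par)
  if (!all(is.finite(ll)))
    .invalid("initialization gives a non-finite likelihood; supply 'init'")

  quad <- if (spatial)
    vapply(1:5, function(p) as.numeric(eps[, p] %*% Qlap %*% eps[, p]),
           numeric(1)) else NULL

  blocks <- c(if (spatial) "tau", "theta",
              if (spatial) paste0("eps_", c("R", "K", "n", "dmean", "dsd")),
              "mu", "kappa", "sigma_eta")
  nb <- length(blocks)
  target <- ifelse(blocks %in% c("mu", "kappa", "sigma_eta"), 0.45, 0.234)
  names(target) <- blocks
  onedim <- blocks %in% c("mu", "kappa", "sigma_eta")

  # adaptation state; initial scales shrink with the lattice size because
  # the pooled likelihood sharpens all global blocks by a factor ~L
  gam <- c(tau = 1, theta = 2.38^2 / 5 / L,
           stats::setNames(rep(0.05^2 / L, 5),
                           paste0("eps_", c("R", "K", "n", "dmean", "dsd"))),
           mu = 2.38^2 / L, kappa = 2.38^2 / L,
           sigma_eta = 2.38^2 / L)[blocks]
  cc <- rep(ctl$c1, nb); names(cc) <- blocks
  # scalar blocks propose on the log scale with sd sqrt(gamma * s2); the
  # fixed base scale keeps the controller's target stationary even when
  # the chain drifts along posterior ridges
  s2one <- c(mu = 0.05^2, kappa = 0.05^2, sigma_eta = 0.05^2)
  Sig_theta <- diag(c(0.01, 0.01, 0.04, 0.25, 0.09))
  R_theta <- chol(Sig_theta)
  Sig_tau <- diag(0.25, 5)
  R_tau <- chol(Sig_tau)
  # empirical covariances are renormalized to these reference determinants
  # so refreshes change only the proposal shape; the adaptive gamma owns
  # the overall scale and its controller never has to re-converge
  logdet_ref <- c(theta = 2 * sum(log(diag(R_theta))),
                  tau = 2 * sum(log(diag(R_tau))))
  .normchol <- function(C, ref) {
    Ck <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(Ck)) return(NULL)
    ld <- 2 * sum(log(diag(Ck)))
    Ck * exp((ref - ld) / (2 * ncol(C)))
  }

  # storage
  theta_draws <- matrix(NA_real_, n_iter, 5L,
                        dimnames = list(NULL, c("R", "K", "n", "dmean",
                                                "dsd")))
  psi_draws <- matrix(NA_real_, n_iter, 5L)
  mu_draws <- kappa_draws <- sig_draws <- ll_trace <- numeric(n_iter)
  tau_draws <- if (spatial) matrix(NA_real_, n_iter, 5L,
                                   dimnames = list(NULL, colnames(theta_draws)))
  eps_draws <- if (spatial) array(NA_real_, c(n_iter, L, 5L))
  accept <- matrix(FALSE, n_iter, nb, dimnames = list(NULL, blocks))
  wins <- rep(0L, nb); names(wins) <- blocks
  postwins <- rep(0L, nb)   # acceptances since burn-in end

  lp_cur <- .lp_theta(psi, priors)

  for (k in seq_len(n_iter)) {
    for (bi in seq_len(nb)) {
      bl <- blocks[bi]
      if (bl == "tau") {
        prop <- ltau + sqrt(gam[bi]) * drop(rnorm(5) %*% R_tau)
        lpost_diff <-
          sum(dnorm(prop, priors$logtau$mean, priors$logtau$sd, log = TRUE) -
              dnorm(ltau, priors$logtau$mean, priors$logtau$sd, log = TRUE)) +
          sum(-(L - 1) / 2 * (prop - ltau) -
              quad / 2 * (exp(-prop) - exp(-ltau)))
        if (is.finite(lpost_diff) && log(runif(1)) < lpost_diff) {
          ltau <- prop; accept[k, bi] <- TRUE; wins[bi] <- wins[bi] + 1L
        }
      } else if (bl == "theta") {
        prop <- psi + sqrt(gam[bi]) * drop(rnorm(5) %*% R_theta)
        lp_prop <- .lp_theta(prop, priors)
        if (is.finite(lp_prop)) {
          par_p <- .build_par(prop, eps, lmu, lkap, lsig, L)
          if (all(par_p[, 5] > 0) && all(par_p[, 5] < tau_max)) {
            ll_p <- loglik(par_p)
            lr <- sum(ll_p) - sum(ll) + lp_prop - lp_cur
            if (is.finite(lr) && log(runif(1)) < lr) {
              psi <- prop; lp_cur <- lp_prop; ll <- ll_p; par <- par_p
              accept[k, bi] <- TRUE; wins[bi] <- wins[bi] + 1L
            }
          }
        }
      } else if (startsWith(bl, "eps_")) {
        p <- match(sub("eps_", "", bl), c("R", "K", "n", "dmean", "dsd"))
        e_p <- eps[, p] + rnorm(L, 0, sqrt(gam[bi]))
        e_p <- e_p - mean(e_p)
        eps_prop <- eps; eps_prop[, p] <- e_p
        par_p <- .build_par(psi, eps_prop, lmu, lkap, lsig, L)
        if (all(par_p[, 5] > 0) && all(par_p[, 5] < tau_max)) {
          q_p <- as.numeric(e_p %*% Qlap %*% e_p)
          ll_p <- loglik(par_p)
          lr <- sum(ll_p) - sum(ll) - (q_p - quad[p]) / (2 * exp(ltau[p]))
          if (is.finite(lr) && log(runif(1)) < lr) {
            eps <- eps_prop; quad[p] <- q_p; ll <- ll_p; par <- par_p
            accept[k, bi] <- TRUE; wins[bi] <- wins[bi] + 1L
          }
        }
      } else {
        # scalar blocks on log scale
        cur <- switch(bl, mu = lmu, kappa = lkap, sigma_eta = lsig)
        prop <- cur + rnorm(1, 0, sqrt(gam[bi] * s2one[bl]))
        lpr_diff <- switch(bl,
          mu = dnorm(prop, priors$logmu$mean, priors$logmu$sd, log = TRUE) -
               dnorm(cur, priors$logmu$mean, priors$logmu$sd, log = TRUE),
          kappa = dnorm(prop, priors$logkappa$mean, priors$logkappa$sd,
                        log = TRUE) -
                  dnorm(cur, priors$logkappa$mean, priors$logkappa$sd,
                        log = TRUE),
          sigma_eta = dnorm(2 * prop, priors$logsig2$mean,
                            priors$logsig2$sd, log = TRUE) -
                      dnorm(2 * cur, priors$logsig2$mean, priors$logsig2$sd,
                            log = TRUE))
        par_p <- .build_par(psi, eps,
                            if (bl == "mu") prop else lmu,
                            if (bl == "kappa") prop else lkap,
                            if (bl == "sigma_eta") prop else lsig, L)
        ll_p <- loglik(par_p)
        lr <- sum(ll_p) - sum(ll) + lpr_diff
        if (is.finite(lr) && log(runif(1)) < lr) {
          if (bl == "mu") lmu <- prop
          else if (bl == "kappa") lkap <- prop
          else lsig <- prop
          ll <- ll_p; par <- par_p
          accept[k, bi] <- TRUE; wins[bi] <- wins[bi] + 1L
        }
      }
    }

    theta_draws[k, ] <- c(exp(psi[1:3]), psi[4], psi[5])
    psi_draws[k, ] <- psi
    mu_draws[k] <- exp(lmu); kappa_draws[k] <- exp(lkap)
    sig_draws[k] <- exp(lsig); ll_trace[k] <- sum(ll)
    if (spatial) {
      tau_draws[k, ] <- exp(ltau)
      eps_draws[k, , ] <- eps
    }

    # Acceptance-rate adaptation.  During burn-in a Robbins-Monro
    # accelerator moves each scale proportionally to the windowed rate
    # error, closing order-of-magnitude initial mismatches within a few
    # hundred iterations.  After burn-in the diminishing multiplicative
    # rule of adapt_scale() is driven by the cumulative empirical
    # acceptance rate of the (post-burn-in) chain, which steers that
    # rate itself onto the target.
    if (k > n_iter %/% 2L)
      postwins <- postwins + as.integer(accept[k, ])
    if (k %% ctl$window == 0L) {
      for (bi in seq_len(nb)) {
        if (k <= n_iter %/% 2L) {
          rate <- wins[bi] / ctl$window
          step <- max(-0.8, min(0.8, 2 * (rate - target[bi])))
          gam[bi] <- gam[bi] * exp(step)
        } else {
          rate <- postwins[bi] / (k - n_iter %/% 2L)
          res <- adapt_scale(gam[bi], cc[bi], rate, target[bi])
          gam[bi] <- res$gamma
          cc[bi] <- res$c
        }
        # keep scales in a sane range (a hyper-variance collapsing to
        # zero would otherwise drag its random-effect proposals with it)
        gam[bi] <- min(max(gam[bi], 1e-10), 1e4)
      }
      wins[] <- 0L
    }

    # empirical covariance refresh from the growing second half of the
    # chain so far (the update itself diminishes as the window grows)
    if (k %% ctl$adapt_cov_every == 0L && k >= 200L) {
      use <- max(1L, k %/% 2L):k
      C <- stats::cov(psi_draws[use, , drop = FALSE])
      C <- 0.9 * C + 0.1 * diag(diag(C)) + 1e-10 * diag(5)
      Ck <- .normchol(C, logdet_ref["theta"])
      if (!is.null(Ck)) R_theta <- Ck
      if (spatial) {
        Ct <- stats::cov(log(tau_draws[use, , drop = FALSE]))
        Ct <- 0.9 * Ct + 0.1 * diag(diag(Ct)) + 1e-10 * diag(5)
        Ck <- .normchol(Ct, logdet_ref["tau"])
        if (!is.null(Ck)) R_tau <- Ck
      }
    }
    if (ctl$verbose && k %% 1000L == 0L)
      message(sprintf("iter %d  logpost %.1f  acc(theta) %.3f", k,
                      ll_trace[k], mean(accept[max(1, k - 999):k, "theta"])))
  }

  structure(list(
    theta = theta_draws, psi = psi_draws, mu = mu_draws,
    kappa = kappa_draws, sigma_eta = sig_draws,
    tau = if (spatial) tau_draws, eps = if (spatial) eps_draws,
    loglik = ll_trace, accept = accept, gamma = gam,
    n_iter = n_iter, burn = n_iter %/% 2L, seed = seed,
    spatial = spatial, L = L, rows = data$rows, cols = data$cols,
    tau_max = tau_max, h = h, exposure = data$exposure,
    mu_global = TRUE), class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d iterations, %d location(s)%s\n",
              x$n_iter, x$L,
              if (x$spatial) sprintf(" (%d x %d)", x$rows, x$cols) else ""))
  cat("  post-burn-in acceptance rates:\n")
  rates <- colMeans(x$accept[(x$burn + 1):x$n_iter, , drop = FALSE])
  for (b in names(rates)) cat(sprintf("    %-12s %.3f\n", b, rates[b]))
  invisible(x)
}

#' Empirical acceptance rate of a block
#'
#' @param chain A [run_mcmc()] result.
#' @param block Block name (e.g. `"theta"`, `"mu"`).
#' @param post_burn Restrict to the post-burn-in half?
#' @return Acceptance fraction.
#' @export
accept_rate <- function(chain, block, post_burn = TRUE) {
  idx <- if (post_burn) (chain$burn + 1L):chain$n_iter
         else seq_len(chain$n_iter)
  mean(chain$accept[idx, block])
}

# per-draw parameter matrix (R, K, n, dmean, dsd) for one location over
# the post-burn-in draws, optionally thinned
.location_draws <- function(chain, location, thin = 1L) {
  idx <- seq(chain$burn + 1L, chain$n_iter, by = thin)
  th <- chain$theta[idx, , drop = FALSE]
  if (chain$spatial) {
    e <- chain$eps[idx, location, , drop = FALSE]
    dim(e) <- c(length(idx), 5L)
    th <- th * exp(e)
  }
  list(theta = th, mu = chain$mu[idx], idx = idx)
}

#' Posterior summaries per location
#'
#' Posterior means and central credible intervals of the per-location
#' kinetic parameters `R`, `K`, `n`, delay mean and delay SD.
#'
#' @param chain A [run_mcmc()] result.
#' @param prob Central interval probability (default 0.9).
#' @param thin Thinning applied to post-burn-in draws.
#' @return A data frame with one row per location and parameter.
#' @export
posterior_summary <- function(chain, prob = 0.9, thin = 1L) {
  a <- (1 - prob) / 2
  out <- vector("list", chain$L)
  for (i in seq_len(chain$L)) {
    d <- .location_draws(chain, i, thin)$theta
    out[[i]] <- data.frame(
      location = i, parameter = colnames(chain$theta),
      mean = colMeans(d),
      lower = apply(d, 2L, quantile, a),
      upper = apply(d, 2L, quantile, 1 - a), row.names = NULL)
  }
  do.call(rbind, out)
}

# minimal random-walk Metropolis used by validation tests of the
# Metropolis kernel itself (fixed scale, no adaptation)
.rwm_chain <- function(logpost, init, n, scale) {
  d <- length(init)
  out <- matrix(NA_real_, n, d)
  cur <- init; lp <- logpost(cur); acc <- 0L
  for (k in seq_len(n)) {
    prop <- cur + rnorm(d, 0, scale)
    lpp <- logpost(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      cur <- prop; lp <- lpp; acc <- acc + 1L
    }
    out[k, ] <- cur
  }
  list(draws = out, rate = acc / n)
}
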