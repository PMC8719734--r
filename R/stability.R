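# Deterministic stability classification of the macroscopic rate equation
# and the posterior robustness estimator.

# Discrete transform of the lagged-state delay operator along a vector of
# complex frequencies: ghat(lam) = sum_k v_k exp(-lam * k * h), evaluated
# by Horner's rule.  This is the operator the simulator and filter apply,
# so the stability analysis is exactly consistent with the simulated
# dynamics (including extreme proposals where truncation matters).
.ghat_discrete <- function(v, h, lam) {
  t1 <- exp(-lam * h)
  acc <- rep(as.complex(v[length(v)]), length(lam))
  for (k in seq(length(v) - 1L, 1L)) acc <- acc * t1 + v[k]
  acc
}

# winding number of F along the closed rectangular contour
# [0, lmax] x [-wmax, wmax]; returns the (real) total argument change / 2pi
# and the minimum |F| relative to its median on the contour
.winding <- function(Ffun, lmax, wmax, npts) {
  s <- seq(0, 1, length.out = npts)
  # counterclockwise: bottom edge, right edge, top edge, left edge
  lam <- c(complex(real = lmax * s, imaginary = -wmax),
           complex(real = lmax, imaginary = -wmax + 2 * wmax * s),
           complex(real = lmax * (1 - s), imaginary = wmax),
           complex(real = 0, imaginary = wmax - 2 * wmax * s))
  Fv <- Ffun(lam)
  ph <- Arg(Fv)
  d <- diff(c(ph, ph[1]))
  d <- d - 2 * pi * round(d / (2 * pi))
  list(winding = sum(d) / (2 * pi),
       rel_min = min(Mod(Fv)) / stats::median(Mod(Fv)),
       max_step = max(abs(d)))
}

#' Classify limit-cycle stability of an oscillator
#'
#' Linearizes the macroscopic rate equation about the equilibrium `x*`:
#' the characteristic function is
#' `F(lambda) = lambda + mu - H'(x*) * ghat(lambda)` where `H'` is the
#' Hill derivative at equilibrium and `ghat` is the transform of the
#' discretized delay operator.  The system is classified as a limit-cycle
#' oscillator (`D = 1`) when `F` has a root with positive real part,
#' detected by the argument principle on a rectangular contour enclosing
#' all candidate unstable roots (the modulus bound
#' `|lambda + mu| <= |H'|` for `Re lambda >= 0` confines them).  Since
#' `F(0) = mu - H'(x*) > 0`, instability can only arise through complex
#' conjugate (Hopf-type) root pairs.  Near-boundary or numerically
#' ambiguous cases fall back to a deterministic simulation oracle.
#'
#' @param params An [oscillator_params()].
#' @param method `"characteristic_root"` (default) or
#'   `"simulation_oracle"`.
#' @param boundary_tol Contour values of `|F|` below this fraction of the
#'   contour median trigger the simulation fallback.
#' @return An object of class `stability_result`: `is_limit_cycle`,
#'   `winding` (number of unstable roots found, `NA` for the oracle) and
#'   `method`.
#' @export
classify_stability <- function(params, method = c("characteristic_root",
                                                  "simulation_oracle"),
                               boundary_tol = 1e-6) {
  method <- match.arg(method)
  if (method == "simulation_oracle")
    return(.stability_sim_oracle(params))
  eq <- .hprime_at_equilibrium(params)
  if (params$n == 0 || eq$hprime == 0)
    return(structure(list(is_limit_cycle = FALSE, winding = 0,
                          method = "characteristic_root"),
                     class = "stability_result"))
  a <- abs(eq$hprime)
  v <- kernel_state_weights(params$kernel)
  h <- params$kernel$grid_step
  Ffun <- function(lam) lam + params$mu - eq$hprime * .ghat_discrete(v, h, lam)
  lmax <- a + 0.1
  wmax <- a + params$mu + 1
  npts <- 512L
  prev <- NULL
  repeat {
    wres <- .winding(Ffun, lmax, wmax, npts)
    wi <- round(wres$winding)
    ok <- abs(wres$winding - wi) < 1e-3 && wres$max_step < pi / 2
    if (wres$rel_min < boundary_tol)
      return(.stability_sim_oracle(params))
    if (ok && !is.null(prev) && prev == wi)
      return(structure(list(is_limit_cycle = wi > 0, winding = wi,
                            method = "characteristic_root"),
                       class = "stability_result"))
    if (ok) prev <- wi else prev <- NULL
    npts <- npts * 2L
    if (npts > 32768L) {
      warning("argument-principle root count did not stabilize; ",
              "falling back to the simulation oracle")
      return(.stability_sim_oracle(params))
    }
  }
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability: %s (%s%s)\n",
              if (x$is_limit_cycle) "limit cycle" else "damped",
              x$method,
              if (!is.na(x$winding)) sprintf(", %d unstable root(s)",
                                             x$winding) else ""))
  invisible(x)
}

# Deterministic-DDE oracle: integrate the macroscopic equation from a 1%
# perturbed equilibrium history for `horizon` hours; growth of the
# deviation over the run indicates a limit cycle, decay a damped
# oscillator.
.stability_sim_oracle <- function(params, dt = 0.1, horizon = 480) {
  p <- set_kernel_step(params, dt)
  xs <- equilibrium_state(p)
  ens <- simulate_paths(p, horizon, dt, n_paths = 1L,
                        init = rep(1.01 * xs, round(p$kernel$tau_max / dt) + 1L),
                        stochastic = FALSE)
  dev <- abs(ens$paths[1L, ] - xs)
  t <- ens$times
  early <- dev[t >= 2 * p$kernel$tau_max & t <= 2 * p$kernel$tau_max + 48]
  late <- dev[t >= horizon - 48]
  structure(list(is_limit_cycle = max(late) > max(early) &&
                   max(late) > 1e-8 * xs,
                 winding = NA_integer_, method = "simulation_oracle"),
            class = "stability_result")
}

# Vectorized simulation oracle over a set of parameter rows
# (R, K, n, mu, dmean, dsd): one deterministic DDE integration per row,
# all rows advanced together.  Returns a logical vector of limit-cycle
# calls by the same growth-vs-decay rule as .stability_sim_oracle.
.stability_sim_oracle_grid <- function(par, tau_max = 24, dt = 0.1,
                                       horizon = 480) {
  L <- nrow(par)
  M <- as.integer(round(tau_max / dt))
  V <- t(vapply(seq_len(L), function(i)
    cpp_state_weights(par[i, 5]^2 / par[i, 6]^2, par[i, 5] / par[i, 6]^2,
                      tau_max, dt), numeric(M + 1L)))
  xs <- vapply(seq_len(L), function(i)
    cpp_equilibrium(par[i, 1], par[i, 2], par[i, 3], par[i, 4]), numeric(1))
  hist <- matrix(1.01 * xs, L, M + 1L)
  nsteps <- as.integer(round(horizon / dt))
  paths <- cpp_sim_paths(hist, par[, 1], par[, 2], par[, 3], par[, 4], V,
                         dt, nsteps, numeric(nsteps), FALSE)
  t <- seq(0, by = dt, length.out = nsteps + 1L)
  dev <- abs(paths - xs)
  early <- t >= 2 * tau_max & t <= 2 * tau_max + 48
  late <- t >= horizon - 48
  a_early <- apply(dev[, early, drop = FALSE], 1L, max)
  a_late <- apply(dev[, late, drop = FALSE], 1L, max)
  a_late > a_early & a_late > 1e-8 * xs
}

#' Posterior robustness of limit-cycle dynamics
#'
#' The robustness statistic is the posterior probability that a
#' location's parameters imply sustained limit-cycle oscillations of the
#' deterministic mean: the binary stability indicator is evaluated at
#' each retained posterior draw and averaged.  The Monte Carlo standard
#' error uses the effective sample size of the indicator chain.
#'
#' @param chain A [run_mcmc()] result.
#' @param location Location index.
#' @param thin Thinning of post-burn-in draws (default targets about 250
#'   stability evaluations).
#' @param tau_max,grid_step Kernel discretization used for the
#'   classification.
#' @return List with `V` (the robustness estimate in `[0, 1]`), `se`,
#'   `n_draws` and the indicator vector `D`.
#' @export
robustness_estimate <- function(chain, location = 1L, thin = NULL,
                                tau_max = chain$tau_max, grid_step = 0.1) {
  npost <- chain$n_iter - chain$burn
  if (npost < 1L) .invalid("chain has no post-burn-in draws")
  if (is.null(thin)) thin <- max(1L, npost %/% 250L)
  d <- .location_draws(chain, location, thin)
  n <- nrow(d$theta)
  D <- logical(n)
  for (t in seq_len(n)) {
    th <- d$theta[t, ]
    if (th["dmean"] >= tau_max || th["dsd"] <= 0) { D[t] <- FALSE; next }
    pp <- oscillator_params(R = th["R"], K = th["K"], n = th["n"],
                            mu = d$mu[t],
                            kernel = delay_kernel_from_moments(
                              th["dmean"], th["dsd"], tau_max, grid_step))
    D[t] <- classify_stability(pp)$is_limit_cycle
  }
  V <- mean(D)
  se <- if (V %in% c(0, 1) || n < 100L) {
    sqrt(V * (1 - V) / n)
  } else {
    ess <- suppressWarnings(effective_sample_size(as.numeric(D)))
    if (ess <= 0) ess <- n
    sqrt(V * (1 - V) / ess)
  }
  list(V = V, se = se, n_draws = n, D = D)
}

#' Stability map over a (Hill coefficient, delay SD) grid
#'
#' Evaluates the binary stability indicator on a grid of Hill
#' coefficients and delay standard deviations with all other parameters
#' fixed, exposing the monotone trade-off: increasing delay dispersion
#' damps the oscillator, and a higher Hill coefficient compensates.
#'
#' @param params_base An [oscillator_params()] providing the fixed
#'   parameters (including the delay mean).
#' @param n_range,sd_range Ordered numeric grids.
#' @return Logical matrix, `length(n_range) x length(sd_range)`.
#' @export
stability_boundary <- function(params_base, n_range, sd_range) {
  dm <- kernel_mean(params_base$kernel)
  k <- params_base$kernel
  out <- matrix(NA, length(n_range), length(sd_range),
                dimnames = list(signif(n_range, 4), signif(sd_range, 4)))
  for (i in seq_along(n_range)) for (j in seq_along(sd_range)) {
    pp <- oscillator_params(R = params_base$R, K = params_base$K,
                            n = n_range[i], mu = params_base$mu,
                            kernel = delay_kernel_from_moments(
                              dm, sd_range[j], k$tau_max, k$grid_step),
                            kappa = params_base$kappa,
                            sigma_eta = params_base$sigma_eta)
    out[i, j] <- classify_stability(pp)$is_limit_cycle
  }
  out
}
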