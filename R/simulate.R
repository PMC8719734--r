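# Euler-Maruyama simulation of the delayed CLE, measurement simulation,
# perturbation injection, synthetic spatio-temporal dataset generation.

#' Rectangular perturbation of mRNA concentration
#'
#' A positive (or negative) shock applied to the drift of the delayed CLE
#' over a rectangular window.  With `mode = "scaled"` (default) the
#' `amplitude` is added as a constant rate in molecules/hour over the
#' window, so the total injected mass is `amplitude * duration` and the
#' duration controls the overall size of the shock.  With
#' `mode = "total"` the total injected mass equals `amplitude` regardless
#' of duration (rate `amplitude/duration`).
#'
#' @param onset Start time in hours (relative to simulation start).
#' @param duration Window length in hours; positive.
#' @param amplitude Shock size in molecules (signed).
#' @param mode `"scaled"` or `"total"`; see Details.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(onset, duration, amplitude,
                         mode = c("scaled", "total")) {
  .check_scalar(onset, "onset", positive = FALSE)
  .check_scalar(duration, "duration")
  .check_scalar(amplitude, "amplitude", positive = FALSE)
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 shape = "rectangular", mode = match.arg(mode)),
            class = "perturbation")
}

# additive drift (molecules/hour) per Euler step implied by a perturbation
.shock_rate_vector <- function(pert, dt, nsteps) {
  shock <- numeric(nsteps)
  if (is.null(pert)) return(shock)
  rate <- if (pert$mode == "scaled") pert$amplitude else
    pert$amplitude / pert$duration
  t0 <- seq_len(nsteps) * dt - dt  # step start times
  on <- t0 + dt / 2 >= pert$onset & t0 + dt / 2 < pert$onset + pert$duration
  shock[on] <- rate
  shock
}

# Initial history buffer (n_paths x (M+1), lag-ordered: column 1 = x(0)).
# "equilibrium": constant at x*.  "limit_cycle": a deterministic pre-run of
# 10 tau_max from a nudged equilibrium so that limit-cycle systems start on
# the attractor.  A numeric vector/matrix is used directly.
.initial_history <- function(init, params, n_paths, dt) {
  M <- as.integer(round(params$kernel$tau_max / dt))
  xs <- equilibrium_state(params)
  if (is.character(init)) {
    init <- match.arg(init, c("equilibrium", "limit_cycle"))
    if (init == "equilibrium")
      return(matrix(xs, n_paths, M + 1L))
    nburn <- as.integer(round(20 * params$kernel$tau_max / dt))
    h0 <- matrix(1.05 * xs, 1L, M + 1L)
    v <- matrix(kernel_state_weights(params$kernel), 1L)
    path <- cpp_sim_paths(h0, params$R, params$K, params$n, params$mu, v,
                          dt, nburn, numeric(nburn), FALSE)
    hist <- rev(path[1L, (nburn + 1L - M):(nburn + 1L)])
    return(matrix(hist, n_paths, M + 1L, byrow = TRUE))
  }
  if (is.matrix(init)) {
    if (ncol(init) != M + 1L || nrow(init) != n_paths)
      .invalid("history matrix must be n_paths x (tau_max/dt + 1)")
    return(init)
  }
  if (length(init) != M + 1L)
    .invalid("history vector must have length tau_max/dt + 1")
  matrix(init, n_paths, M + 1L, byrow = TRUE)
}

#' Simulate trajectories of the delayed CLE
#'
#' Euler-Maruyama integration of the delayed chemical Langevin equation:
#' `X(t+dt) = X(t) + drift dt + sqrt(variance rate * dt) * xi`, with the
#' delayed integral computed from a rolling history buffer using the
#' kernel's lagged-state weights and negative excursions clamped at zero.
#' The Euler step must equal the kernel grid step (use
#' [set_kernel_step()] to rediscretize).
#'
#' @param params An [oscillator_params()].
#' @param horizon Simulated duration in hours.
#' @param dt Euler step in hours; must equal `params$kernel$grid_step`.
#' @param n_paths Number of independent paths.
#' @param init Initial history: `"equilibrium"`, `"limit_cycle"`, or a
#'   numeric vector / `n_paths x (tau_max/dt + 1)` matrix of lagged states
#'   (most recent first).
#' @param perturbation Optional [perturbation()].
#' @param seed Integer RNG seed; required when `stochastic = TRUE`.
#' @param stochastic Include the Wiener noise term?  `FALSE` integrates
#'   the macroscopic (deterministic mean) equation.
#' @return An object of class `trajectory_ensemble` with `times`, `paths`
#'   (`n_paths x n_times`), `dt`, `history`, `seed` and `params`.
#' @export
simulate_paths <- function(params, horizon, dt = params$kernel$grid_step,
                           n_paths = 1L, init = "equilibrium",
                           perturbation = NULL, seed = NULL,
                           stochastic = TRUE) {
  if (abs(dt - params$kernel$grid_step) > 1e-10)
    .invalid("'dt' must equal the kernel grid step; see set_kernel_step()")
  if (stochastic && is.null(seed))
    .invalid("a 'seed' is required for stochastic simulation")
  nsteps <- as.integer(round(horizon / dt))
  if (nsteps < 1L) .invalid("'horizon' too short")
  hist <- .initial_history(init, params, n_paths, dt)
  v <- matrix(kernel_state_weights(params$kernel), 1L)
  shock <- .shock_rate_vector(perturbation, dt, nsteps)
  if (!is.null(seed)) set.seed(seed)
  paths <- cpp_sim_paths(hist, params$R, params$K, params$n, params$mu, v,
                         dt, nsteps, shock, stochastic)
  structure(list(times = seq(0, by = dt, length.out = nsteps + 1L),
                 paths = paths, dt = dt, history = hist,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 params = params),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d path(s), %d steps of %g h (%g h)\n",
              nrow(x$paths), ncol(x$paths) - 1L, x$dt,
              max(x$times)))
  invisible(x)
}

#' Simulate the bioluminescence measurement process
#'
#' Each recorded frame is `kappa` times the trapezoid integral of the
#' molecular path over the exposure window, plus independent Gaussian
#' read noise with standard deviation `sigma_eta`.
#'
#' @param ensemble A [simulate_paths()] result.
#' @param params An [oscillator_params()] supplying `kappa` and
#'   `sigma_eta`.
#' @param exposure Frame exposure in hours; an integer multiple of the
#'   ensemble `dt`.
#' @param seed Integer RNG seed for the read noise (optional; omit for
#'   noise-free output only when `sigma_eta = 0`).
#' @return A `luminescence_record`: `values` (paths x frames), `exposure`,
#'   and lattice `rows`/`cols` (here `NA`; set by the lattice generator).
#' @export
simulate_observation <- function(ensemble, params, exposure, seed = NULL) {
  r <- exposure / ensemble$dt
  if (abs(r - round(r)) > 1e-8)
    .invalid("'exposure' must be an integer multiple of dt")
  r <- as.integer(round(r))
  X <- ensemble$paths
  n_frames <- (ncol(X) - 1L) %/% r
  if (n_frames < 2L) .invalid("ensemble too short for 2 frames")
  tw <- rep(ensemble$dt, r + 1L)
  tw[c(1L, r + 1L)] <- ensemble$dt / 2
  vals <- matrix(0, nrow(X), n_frames)
  for (f in seq_len(n_frames)) {
    idx <- ((f - 1L) * r + 1L):(f * r + 1L)
    vals[, f] <- params$kappa * (X[, idx, drop = FALSE] %*% tw)
  }
  if (params$sigma_eta > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + matrix(rnorm(length(vals), 0, params$sigma_eta),
                          nrow(vals))
  }
  luminescence_record(vals, exposure)
}

#' Luminescence record container
#'
#' Observed (or simulated) light intensities, one row per location and
#' one column per frame, with exposure metadata and an optional lattice
#' layout (row-major location order).
#'
#' @param values Numeric matrix, locations x frames.
#' @param exposure Frame exposure in hours.
#' @param rows,cols Lattice dimensions (optional).
#' @export
luminescence_record <- function(values, exposure, rows = NA_integer_,
                                cols = NA_integer_) {
  values <- as.matrix(values)
  .check_scalar(exposure, "exposure")
  if (ncol(values) < 2L) .invalid("a record needs at least 2 frames")
  structure(list(values = values, exposure = exposure,
                 rows = rows, cols = cols),
            class = "luminescence_record")
}

#' @export
print.luminescence_record <- function(x, ...) {
  lay <- if (is.na(x$rows)) "" else sprintf(" (%d x %d lattice)",
                                            x$rows, x$cols)
  cat(sprintf("Luminescence record: %d location(s)%s, %d frames at %g h\n",
              nrow(x$values), lay, ncol(x$values), x$exposure))
  invisible(x)
}

#' Generate a synthetic spatio-temporal dataset
#'
#' Samples multiplicative random effects for `R`, `K`, `n`, delay mean and
#' delay SD from the sum-to-zero constrained CAR prior on the lattice,
#' forms per-location parameters `theta_i = theta * exp(eps_i)`, simulates
#' one stochastic trajectory per location from a settled (deterministic
#' pre-run) history, and applies the measurement model.  Ground truth is
#' returned for recovery experiments.
#'
#' @param rows,cols Lattice dimensions (each at least 2).
#' @param global_params An [oscillator_params()] holding the global means.
#' @param hyper_variances Named positive vector of CAR conditional
#'   variance scales for `R`, `K`, `n`, `dmean`, `dsd`.
#' @param horizon Recording length in hours (default 125 h: 250 frames at
#'   0.5 h exposure).
#' @param exposure Frame exposure in hours.
#' @param dt Euler step for the underlying paths.
#' @param seed Integer RNG seed.
#' @return List with `record` (a `luminescence_record`), `field` (the true
#'   [spatial_field()]) and `ensemble` (the true trajectories).
#' @export
generate_synthetic_dataset <- function(rows, cols, global_params,
                                       hyper_variances = c(R = 0.005,
                                                           K = 0.005,
                                                           n = 0.005,
                                                           dmean = 0.002,
                                                           dsd = 0.005),
                                       horizon = 125, exposure = 0.5,
                                       dt = 0.1, seed) {
  if (rows < 2L || cols < 2L) .invalid("lattice must be at least 2 x 2")
  if (length(hyper_variances) != 5L)
    .invalid("'hyper_variances' needs one entry per spatial parameter")
  if (any(!is.finite(hyper_variances)) || any(hyper_variances <= 0))
    .invalid("hyper-variances must be positive")
  if (missing(seed)) .invalid("a 'seed' is required")
  set.seed(seed)
  L <- rows * cols
  theta <- c(R = global_params$R, K = global_params$K, n = global_params$n,
             dmean = kernel_mean(global_params$kernel),
             dsd = kernel_sd(global_params$kernel))
  if (!is.null(names(hyper_variances)))
    hyper_variances <- hyper_variances[names(theta)]
  names(hyper_variances) <- names(theta)
  field <- spatial_field(rows, cols, theta = theta, tau = hyper_variances)
  field$eps <- vapply(seq_len(5L),
                      function(p) sample_car_field(field, field$tau[p]),
                      numeric(L))
  colnames(field$eps) <- names(theta)
  par_loc <- apply_random_effects(theta, field$eps)
  tau_max <- global_params$kernel$tau_max
  if (any(par_loc[, "dmean"] >= tau_max))
    .invalid("sampled delay means exceed tau_max; reduce hyper-variances")

  M <- as.integer(round(tau_max / dt))
  V <- t(vapply(seq_len(L), function(i)
    cpp_state_weights(par_loc[i, "dmean"]^2 / par_loc[i, "dsd"]^2,
                      par_loc[i, "dmean"] / par_loc[i, "dsd"]^2,
                      tau_max, dt), numeric(M + 1L)))
  xs <- vapply(seq_len(L), function(i)
    cpp_equilibrium(par_loc[i, "R"], par_loc[i, "K"], par_loc[i, "n"],
                    global_params$mu), numeric(1))
  # deterministic settling run so limit-cycle locations start on-cycle
  nburn <- as.integer(round(20 * tau_max / dt))
  h0 <- matrix(1.05 * xs, L, M + 1L)
  burn <- cpp_sim_paths(h0, par_loc[, "R"], par_loc[, "K"], par_loc[, "n"],
                        rep(global_params$mu, L), V, dt, nburn,
                        numeric(nburn), FALSE)
  hist <- burn[, (nburn + 1L - M):(nburn + 1L), drop = FALSE]
  hist <- hist[, (M + 1L):1L, drop = FALSE]  # lag order
  nsteps <- as.integer(round(horizon / dt))
  paths <- cpp_sim_paths(hist, par_loc[, "R"], par_loc[, "K"],
                         par_loc[, "n"], rep(global_params$mu, L), V, dt,
                         nsteps, numeric(nsteps), TRUE)
  ens <- structure(list(times = seq(0, by = dt, length.out = nsteps + 1L),
                        paths = paths, dt = dt, history = hist,
                        seed = seed, params = global_params),
                   class = "trajectory_ensemble")
  rec <- simulate_observation(ens, global_params, exposure)
  rec$rows <- rows; rec$cols <- cols
  list(record = rec, field = field, ensemble = ens,
       location_params = par_loc)
}
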