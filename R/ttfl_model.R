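# Single-cell transcription-degradation model: Hill repression, CLE
# drift/diffusion, macroscopic rate equation, equilibrium.

#' Oscillator parameters
#'
#' Parameter set of the single-cell delayed negative feedback loop:
#' maximum transcription rate `R` (molecules/hour), dissociation
#' coefficient `K` (molecules), Hill coefficient `n` (dimensionless,
#' `n >= 0`), degradation rate `mu` (per hour), the gamma delay kernel,
#' the light scaling `kappa` (light units per molecule-hour) between
#' integrated mRNA and the recorded bioluminescence signal, and the
#' measurement noise standard deviation `sigma_eta` (light units).
#'
#' @param R,K,n,mu Kinetic parameters; all positive except `n >= 0`.
#' @param kernel A [delay_kernel()].
#' @param kappa,sigma_eta Measurement model parameters; positive.
#' @return An object of class `oscillator_params`.
#' @seealso [reference_params()] for the two prototypical oscillator types.
#' @export
oscillator_params <- function(R, K, n, mu, kernel, kappa = 2.5e-3,
                              sigma_eta = exp(-5.3 / 2)) {
  .check_scalar(R, "R"); .check_scalar(K, "K"); .check_scalar(mu, "mu")
  .check_scalar(kappa, "kappa"); .check_scalar(sigma_eta, "sigma_eta")
  .check_scalar(n, "n", positive = FALSE)
  if (n < 0) .invalid("'n' must be non-negative")
  if (!inherits(kernel, "delay_kernel"))
    .invalid("'kernel' must be a delay_kernel")
  structure(list(R = R, K = K, n = n, mu = mu, kernel = kernel,
                 kappa = kappa, sigma_eta = sigma_eta),
            class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat(sprintf(
    "TTFL oscillator: R = %.4g /h, K = %.4g, n = %.3g, mu = %.3g /h\n",
    x$R, x$K, x$n, x$mu))
  cat(sprintf("  delay mean %.3g h, sd %.3g h; kappa = %.3g, sigma_eta = %.3g\n",
              kernel_mean(x$kernel), kernel_sd(x$kernel), x$kappa,
              x$sigma_eta))
  invisible(x)
}

#' Prototypical oscillator parameter sets
#'
#' The two limit-cycle oscillator prototypes used throughout the ensemble
#' perturbation studies.  Both share `R = 50`, `K = 100`, `mu = 0.25`;
#' Type I has Hill coefficient 3.82 with delay mean 9.1 h and SD 2.2 h
#' (a concentrated, switch-like inhibition), Type II has Hill coefficient
#' 5.57 with delay mean 9.4 h and SD 4.2 h (inhibition distributed over a
#' wider lag window).
#'
#' @param type `"I"` or `"II"`.
#' @param grid_step Kernel discretization step in hours.
#' @param tau_max Kernel truncation bound in hours.
#' @return An [oscillator_params()] object.
#' @export
reference_params <- function(type = c("II", "I"), grid_step = 0.5,
                             tau_max = 24) {
  type <- match.arg(type)
  if (type == "I")
    oscillator_params(R = 50, K = 100, n = 3.82, mu = 0.25,
                      kernel = delay_kernel_from_moments(9.1, 2.2, tau_max,
                                                        grid_step))
  else
    oscillator_params(R = 50, K = 100, n = 5.57, mu = 0.25,
                      kernel = delay_kernel_from_moments(9.4, 4.2, tau_max,
                                                        grid_step))
}

#' Hill repression rate
#'
#' Transcription rate `R / (1 + (z/K)^n)` as a function of the delayed
#' transcription-factor proxy `z`; strictly decreasing in `z` for
#' `n > 0` and constant `R/2` at `z = K`.
#'
#' @param z Delayed mRNA level, molecules; non-negative (vectorized).
#' @param params An [oscillator_params()].
#' @return Transcription rate in molecules/hour.
#' @export
hill_rate <- function(z, params) {
  if (any(!is.finite(z)) || any(z < 0))
    .invalid("'z' must be non-negative and finite")
  if (params$n == 0) return(rep(params$R / 2, length(z)))
  params$R / (1 + (z / params$K)^params$n)
}

#' @rdname hill_rate
#' @description `hill_derivative` gives the derivative of the repression
#'   function with respect to `z`; it is non-positive.
#' @export
hill_derivative <- function(z, params) {
  if (any(!is.finite(z)) || any(z < 0))
    .invalid("'z' must be non-negative and finite")
  if (params$n == 0) return(rep(0, length(z)))
  u <- (z / params$K)^params$n
  out <- ifelse(z > 0, -params$R * params$n * u / (z * (1 + u)^2), 0)
  out
}

#' Equilibrium of the macroscopic rate equation
#'
#' The unique positive root of `R/(1 + (x/K)^n) = mu * x`: under the
#' normalized delay kernel the delayed integral of a constant history is
#' that constant, so the equilibrium does not involve the delay.  Solved
#' by bisection to a relative tolerance of 1e-12.
#'
#' @param params An [oscillator_params()].
#' @return Equilibrium copy number `x*` (molecules).
#' @export
equilibrium_state <- function(params) {
  cpp_equilibrium(params$R, params$K, params$n, params$mu)
}

#' CLE drift and diffusion
#'
#' Drift (net propensity) and diffusion variance rate (sum of birth and
#' death propensities, the square of the chemical-Langevin noise
#' coefficient) at current state `x_now` with delayed proxy `z_delayed`.
#'
#' @param x_now,z_delayed Current and delayed mRNA levels, molecules.
#' @param params An [oscillator_params()].
#' @return List with `drift` (molecules/hour) and
#'   `diffusion_variance_rate` (molecules^2/hour).
#' @export
cle_drift_diffusion <- function(x_now, z_delayed, params) {
  if (any(x_now < 0) || any(z_delayed < 0))
    .invalid("states must be non-negative")
  hr <- hill_rate(z_delayed, params)
  list(drift = hr - params$mu * x_now,
       diffusion_variance_rate = hr + params$mu * x_now)
}

#' Right-hand side of the macroscopic rate equation
#'
#' Deterministic mean equation of the delayed CLE:
#' `H(integral of history against the delay kernel) - mu * history(t)`,
#' with the delayed integral computed by the kernel's midpoint masses.
#' `history` must be defined on `[t - tau_max, t]`.
#'
#' @param history Function of time returning molecules.
#' @param t Time in hours.
#' @param params An [oscillator_params()].
#' @return Rate of change in molecules/hour.
#' @export
macroscopic_rhs <- function(history, t, params) {
  k <- params$kernel
  past <- tryCatch(history(t - k$midpoints),
                   error = function(e) .invalid(
                     "history does not cover [t - tau_max, t]"))
  if (length(past) != length(k$midpoints) || any(!is.finite(past)))
    .invalid("history does not cover [t - tau_max, t]")
  z <- sum(k$weights * past)
  hill_rate(z, params) - params$mu * history(t)
}

# per-hour slope of the repression function at equilibrium; <= 0
.hprime_at_equilibrium <- function(params) {
  xs <- equilibrium_state(params)
  list(xstar = xs, hprime = hill_derivative(xs, params))
}

#' Replace the kernel discretization step
#'
#' Returns the same oscillator with its delay kernel rediscretized at a
#' new grid step (simulation requires the Euler step to equal the kernel
#' step).
#'
#' @param params An [oscillator_params()].
#' @param grid_step New step in hours.
#' @export
set_kernel_step <- function(params, grid_step) {
  params$kernel <- delay_kernel(params$kernel$shape, params$kernel$rate,
                                params$kernel$tau_max, grid_step)
  params
}
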