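# Gamma-distributed transcriptional delay: truncation, discretization,
# moments, entropy and Laplace transform.

#' Gamma delay kernel
#'
#' Construct the gamma-distributed transcriptional delay used by the
#' delayed feedback model.  The continuous gamma density with the given
#' shape and rate is truncated at `tau_max`, renormalized to integrate to
#' one, and discretized into probability masses on a uniform grid of step
#' `grid_step` (cell masses attributed to cell midpoints).  The
#' renormalization makes the delayed integral a proper weighted average,
#' so a constant history maps exactly to itself at equilibrium.
#'
#' A kernel whose standard deviation is smaller than one grid cell is
#' represented by a point mass on the cell containing the mean, which
#' preserves the fixed-delay model as a limiting case.
#'
#' @param shape,rate Shape (dimensionless) and rate (1/hours) of the gamma
#'   density; both must be positive.
#' @param tau_max Truncation bound in hours.  Defaults to 24.
#' @param grid_step Discretization step in hours; must divide `tau_max`.
#' @return An object of class `delay_kernel` with fields `shape`, `rate`,
#'   `tau_max`, `grid_step`, `weights` (cell masses summing to one) and
#'   `midpoints` (cell midpoints in hours).
#' @seealso [delay_kernel_from_moments()], [kernel_entropy()],
#'   [kernel_laplace()]
#' @examples
#' k <- delay_kernel(shape = 5, rate = 0.5)
#' sum(k$weights)
#' kernel_mean(k)
#' @export
delay_kernel <- function(shape, rate, tau_max = 24, grid_step = 0.5) {
  .check_scalar(shape, "shape")
  .check_scalar(rate, "rate")
  .check_scalar(tau_max, "tau_max")
  .check_scalar(grid_step, "grid_step")
  M <- tau_max / grid_step
  if (abs(M - round(M)) > 1e-8)
    .invalid("'grid_step' must divide 'tau_max'")
  M <- as.integer(round(M))
  if (M < 2L) .invalid("kernel grid must have at least 2 cells")
  w <- cpp_kernel_masses(shape, rate, tau_max, grid_step)
  structure(
    list(shape = shape, rate = rate, tau_max = tau_max,
         grid_step = grid_step, weights = w,
         midpoints = (seq_len(M) - 0.5) * grid_step),
    class = "delay_kernel")
}

#' Delay kernel from mean and standard deviation
#'
#' Moment parameterization of [delay_kernel()]: shape = mean^2/sd^2 and
#' rate = mean/sd^2 reproduce the requested (untruncated) mean and SD.
#'
#' @param mean,sd Delay mean and standard deviation in hours; positive.
#' @inheritParams delay_kernel
#' @return A `delay_kernel`.
#' @examples
#' k <- delay_kernel_from_moments(9.4, 4.2)
#' c(k$shape, k$rate)
#' @export
delay_kernel_from_moments <- function(mean, sd, tau_max = 24,
                                      grid_step = 0.5) {
  .check_scalar(mean, "mean")
  .check_scalar(sd, "sd")
  .check_scalar(tau_max, "tau_max")
  if (tau_max < mean)
    .invalid("'tau_max' must be at least the delay mean")
  delay_kernel(shape = mean^2 / sd^2, rate = mean / sd^2,
               tau_max = tau_max, grid_step = grid_step)
}

#' @export
print.delay_kernel <- function(x, ...) {
  cat(sprintf(
    "Gamma delay kernel: shape %.4g, rate %.4g /h (mean %.3g h, sd %.3g h)\n",
    x$shape, x$rate, kernel_mean(x), kernel_sd(x)))
  cat(sprintf("  truncated at %g h, %d cells of %g h\n",
              x$tau_max, length(x$weights), x$grid_step))
  invisible(x)
}

#' Untruncated moments of a delay kernel
#'
#' @param kernel A `delay_kernel`.
#' @return Mean (`kernel_mean`) or standard deviation (`kernel_sd`) in
#'   hours of the untruncated gamma density.
#' @export
kernel_mean <- function(kernel) kernel$shape / kernel$rate

#' @rdname kernel_mean
#' @export
kernel_sd <- function(kernel) sqrt(kernel$shape) / kernel$rate

# Midpoint quadrature nodes in probability space: substituting
# u = pgamma(s) turns integrals of f(s) against the truncated density into
# plain averages of f(qgamma(u)) over u in (0, Z), which is robust for
# arbitrarily narrow kernels.
.kernel_unodes <- function(kernel, n = 4096L) {
  Z <- pgamma(kernel$tau_max, kernel$shape, kernel$rate)
  u <- (seq_len(n) - 0.5) / n * Z
  list(s = qgamma(u, kernel$shape, kernel$rate), Z = Z)
}

#' Differential entropy of the delay distribution
#'
#' Entropy (in nats) of the truncated, renormalized delay density,
#' \eqn{-\int_0^{\tau_{max}} g(s) \log g(s)\, ds}, evaluated by quadrature
#' on the continuous density (density values, not cell masses, appear
#' inside the logarithm).  The entropy summarizes the dispersion of the
#' delay: a narrower kernel at the same mean has strictly smaller entropy.
#'
#' @param kernel A `delay_kernel`.
#' @param n Number of quadrature nodes.
#' @return Entropy in nats.
#' @examples
#' kernel_entropy(delay_kernel(1, 1))  # exponential: 1 - log(rate) = 1
#' @export
kernel_entropy <- function(kernel, n = 4096L) {
  q <- .kernel_unodes(kernel, n)
  -mean(dgamma(q$s, kernel$shape, kernel$rate, log = TRUE) - log(q$Z))
}

#' Laplace transform of the delay kernel
#'
#' \eqn{\hat g(\lambda) = \int_0^{\tau_{max}} e^{-\lambda s} g(s)\, ds}
#' over the truncated, renormalized density.  `method = "quadrature"`
#' (default) integrates the continuous density; `method = "discrete"`
#' returns the transform of the discretized delayed-integral operator
#' actually applied to lagged states by the simulator and filter, which is
#' what the stability analysis uses for exact consistency with the
#' simulated dynamics.
#'
#' @param kernel A `delay_kernel`.
#' @param lam Complex (or real) frequency, per hour.  Vectorized.
#' @param method `"quadrature"` or `"discrete"`.
#' @param n Quadrature nodes for `method = "quadrature"`.
#' @return Complex vector of transform values; `lam = 0` gives 1.
#' @export
kernel_laplace <- function(kernel, lam, method = c("quadrature", "discrete"),
                           n = 4096L) {
  method <- match.arg(method)
  if (method == "quadrature") {
    q <- .kernel_unodes(kernel, n)
    vapply(as.complex(lam),
           function(l) mean(exp(-l * q$s)),
           complex(1))
  } else {
    v <- kernel_state_weights(kernel)
    h <- kernel$grid_step
    vapply(as.complex(lam), function(l) {
      t1 <- exp(-l * h)
      acc <- as.complex(v[length(v)])
      for (k in seq(length(v) - 1L, 1L)) acc <- acc * t1 + v[k]
      acc
    }, complex(1))
  }
}

#' Lagged-state weights of the discretized delayed integral
#'
#' Weights `v` such that `sum(v[k] * x(t - (k-1) h))` approximates the
#' delayed integral of the kernel, with each midpoint mass split between
#' its two bracketing grid states.  This is the operator shared by the
#' simulator, the filter and the stability analysis.
#'
#' @param kernel A `delay_kernel`.
#' @return Numeric vector of length `tau_max/grid_step + 1` summing to 1.
#' @export
kernel_state_weights <- function(kernel) {
  cpp_state_weights(kernel$shape, kernel$rate, kernel$tau_max,
                    kernel$grid_step)
}
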