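# Multiplicative random effects on a lattice with a first-order intrinsic
# Gaussian CAR (conditional autoregressive) prior and sum-to-zero
# constraint.

#' Queen (8-neighbour) adjacency of a lattice
#'
#' Builds the 0/1 adjacency matrix of the full `rows x cols` lattice with
#' 8-neighbourhood (horizontal, vertical and diagonal) and no wraparound;
#' interior cells have 8 neighbours, edges 5, corners 3.  Locations are
#' indexed row-major.
#'
#' @param rows,cols Lattice dimensions, each at least 2.
#' @return A symmetric 0/1 matrix with zero diagonal.
#' @export
build_adjacency <- function(rows, cols) {
  if (rows < 2L || cols < 2L) .invalid("lattice must be at least 2 x 2")
  L <- rows * cols
  idx <- function(r, c) (r - 1L) * cols + c
  W <- matrix(0L, L, L)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1L && r2 <= rows && c2 >= 1L && c2 <= cols)
        W[idx(r, c), idx(r2, c2)] <- 1L
    }
  }
  W
}

#' Spatial random-effects field
#'
#' Container for the lattice layout, its queen adjacency, the global
#' parameter means `theta` (`R`, `K`, `n`, delay mean, delay SD), the
#' per-parameter random effects `eps` (one column per parameter, each
#' summing to zero) and the CAR hyper-variance scales `tau`.
#'
#' @param rows,cols Lattice dimensions.
#' @param theta Named numeric vector of global means.
#' @param eps Optional `L x 5` matrix of random effects (default zero).
#' @param tau Named positive vector of hyper-variance scales.
#' @return An object of class `spatial_field`.
#' @export
spatial_field <- function(rows, cols,
                          theta = c(R = 50, K = 100, n = 5.57,
                                    dmean = 9.4, dsd = 4.2),
                          eps = NULL,
                          tau = c(R = 0.01, K = 0.01, n = 0.01,
                                  dmean = 0.01, dsd = 0.01)) {
  W <- build_adjacency(rows, cols)
  L <- rows * cols
  if (is.null(eps)) eps <- matrix(0, L, 5L,
                                  dimnames = list(NULL, names(theta)))
  if (any(tau <= 0)) .invalid("'tau' must be positive")
  structure(list(rows = rows, cols = cols, W = W,
                 neighbor_counts = colSums(W), theta = theta,
                 eps = eps, tau = tau),
            class = "spatial_field")
}

#' @export
print.spatial_field <- function(x, ...) {
  cat(sprintf("Spatial field: %d x %d lattice (%d locations)\n",
              x$rows, x$cols, x$rows * x$cols))
  cat("  global means:",
      paste(sprintf("%s = %.4g", names(x$theta), x$theta), collapse = ", "),
      "\n")
  invisible(x)
}

#' Conditional CAR prior of one random effect
#'
#' Given all other random effects, the prior of the effect at location
#' `i` is Gaussian with mean equal to the average of its neighbours'
#' effects and variance `tau / w_i+` where `w_i+` is the neighbour count:
#' more neighbours mean a tighter conditional.
#'
#' @param i Location index.
#' @param eps Random-effect vector for one parameter.
#' @param tau Positive conditional variance scale.
#' @param field A [spatial_field()].
#' @return List with `mean` and `variance`.
#' @export
car_conditional <- function(i, eps, tau, field) {
  w <- field$neighbor_counts[i]
  if (w == 0) .invalid("location has no neighbours")
  list(mean = sum(field$W[i, ] * eps) / w, variance = tau / w)
}

# sum of squared differences over neighbour pairs (each pair once)
.car_quadform <- function(eps, W) {
  D <- diag(colSums(W))
  as.numeric(eps %*% (D - W) %*% eps)  # = sum_{i<j, w=1} (eps_i - eps_j)^2
}

#' Joint (improper) CAR log-prior
#'
#' Pairwise-difference form of the intrinsic CAR prior:
#' `-(1/(2 tau)) * sum over neighbour pairs of (eps_i - eps_j)^2`
#' plus the rank-deficient normalizing term `((L-1)/2) * log(1/tau)`,
#' up to an additive constant.  The joint prior is improper; the
#' sum-to-zero constraint makes the model identifiable.
#'
#' @param eps Random-effect vector summing to zero (tolerance 1e-10).
#' @param tau Positive variance scale.
#' @param field A [spatial_field()].
#' @return Log-density up to an additive constant.
#' @export
car_logprior <- function(eps, tau, field) {
  .check_scalar(tau, "tau")
  if (abs(sum(eps)) > 1e-10 * max(1, max(abs(eps))))
    .invalid("'eps' must sum to zero")
  L <- length(eps)
  -(0.5 / tau) * .car_quadform(eps, field$W) - ((L - 1) / 2) * log(tau)
}

#' Apply multiplicative random effects
#'
#' Per-location parameters `theta_i = theta * exp(eps_i)`, elementwise per
#' parameter.  Under the sum-to-zero constraint the geometric mean over
#' locations equals the global mean.
#'
#' @param theta Named global-mean vector.
#' @param eps `L x length(theta)` matrix of random effects.
#' @return `L x length(theta)` matrix of per-location parameters.
#' @export
apply_random_effects <- function(theta, eps) {
  eps <- as.matrix(eps)
  if (ncol(eps) != length(theta)) .invalid("shape mismatch")
  out <- sweep(exp(eps), 2L, theta, `*`)
  colnames(out) <- names(theta)
  out
}

#' Sample one random-effect field from the constrained CAR prior
#'
#' Draws from the intrinsic CAR prior restricted to the sum-to-zero
#' subspace by spectral decomposition of the graph Laplacian `D - W`:
#' coefficients along eigenvectors with eigenvalue `lambda > 0` are
#' independent Gaussians with variance `tau / lambda`.
#'
#' @param field A [spatial_field()].
#' @param tau Positive variance scale.
#' @return Numeric vector of length `L` summing to zero (within round-off;
#'   re-centred exactly).
#' @export
sample_car_field <- function(field, tau) {
  .check_scalar(tau, "tau")
  Q <- diag(field$neighbor_counts) - field$W
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(e$values)
  z <- rnorm(sum(pos), 0, sqrt(tau / e$values[pos]))
  eps <- as.numeric(e$vectors[, pos, drop = FALSE] %*% z)
  eps - mean(eps)
}
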