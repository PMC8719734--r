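# The Inhibition Profile: lag-resolved relative inhibition of
# transcription by past mRNA, its total and the entropy of the
# standardized profile.

#' Inhibition Profile of transcriptional regulation
#'
#' The Inhibition Profile at lag `k` is the negative gradient of the
#' transcription rate with respect to mRNA `k` hours in the past,
#' evaluated at and divided by the equilibrium `x*`:
#' `IP(k) = -H'(x*) g(k) / x*`, since the functional derivative of the
#' delayed integral with respect to `x(-k)` is the delay density `g(k)`.
#' The standardized profile `IP/total` therefore equals the truncated
#' delay density itself: a low delay dispersion concentrates the
#' inhibitory response near the delay mean (a fast transcriptional
#' on-off switch), a high dispersion spreads it over the cycle.
#'
#' @param params An [oscillator_params()] with `n > 0` (for `n = 0` the
#'   profile is identically zero and a warning is issued).
#' @return An object of class `inhibition_profile`: `lags` (hours),
#'   `values` (per molecule per hour, at the kernel cell midpoints),
#'   `total` (integral over lags, per molecule per hour),
#'   `entropy_standardized` (nats) and the underlying `kernel`.
#' @export
compute_ip <- function(params) {
  k <- params$kernel
  if (params$n == 0) {
    warning("n = 0: no feedback, inhibition profile is zero")
    return(structure(list(lags = k$midpoints,
                          values = numeric(length(k$midpoints)),
                          total = 0, entropy_standardized = NA_real_,
                          kernel = k, scale = 0),
                     class = "inhibition_profile"))
  }
  eq <- .hprime_at_equilibrium(params)
  A <- -eq$hprime / eq$xstar              # per molecule per hour
  # cell-averaged density values: mass / width
  dens <- k$weights / k$grid_step
  structure(list(lags = k$midpoints, values = A * dens, total = A,
                 entropy_standardized = kernel_entropy(k), kernel = k,
                 scale = A),
            class = "inhibition_profile")
}

#' @export
print.inhibition_profile <- function(x, ...) {
  cat(sprintf(
    "Inhibition profile: total %.4g per molecule per hour, entropy %.4g nats\n",
    x$total, x$entropy_standardized))
  invisible(x)
}

#' Entropy of the standardized Inhibition Profile
#'
#' Differential entropy (nats) of the profile standardized to integrate
#' to one, computed by quadrature on the continuous profile density (as
#' for the delay kernel entropy).  Because the standardized profile
#' equals the delay density, this coincides with [kernel_entropy()] and
#' is invariant to rescaling the transcription rate.
#'
#' @param profile A [compute_ip()] result with positive total.
#' @param n Quadrature nodes.
#' @return Entropy in nats.
#' @export
ip_entropy <- function(profile, n = 4096L) {
  if (!is.finite(profile$total) || profile$total <= 0)
    .invalid("zero or invalid profile: entropy undefined")
  k <- profile$kernel
  q <- .kernel_unodes(k, n)
  ipvals <- profile$scale *
    exp(dgamma(q$s, k$shape, k$rate, log = TRUE) - log(q$Z))
  -mean(log(ipvals / profile$total))
}

#' Total inhibition
#'
#' Integral of the Inhibition Profile over lags (quadrature of the cell
#' values times the cell width); analytically `-H'(x*)/x*`, increasing in
#' the Hill coefficient at fixed `x*/K`, and zero without feedback.
#'
#' @param profile A [compute_ip()] result.
#' @return Total inhibition, per molecule per hour.
#' @export
total_inhibition <- function(profile) {
  sum(profile$values) * profile$kernel$grid_step
}
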