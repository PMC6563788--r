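#' PSP normalization constant
#'
#' Scaling factor that stretches the peak of the double-exponential
#' postsynaptic-potential kernel to one. With \eqn{\beta = \tau_m/\tau_s},
#' the factor is \eqn{\beta^{\beta/(\beta-1)} / (\beta-1)}.
#'
#' @param tau_m membrane time constant (ms).
#' @param tau_s synaptic current time constant (ms); must satisfy
#'   `tau_m > tau_s > 0`.
#' @return the dimensionless normalization factor.
#' @examples
#' v_norm(10, 2.5)  # 4^(4/3)/3
#' @export
v_norm <- function(tau_m, tau_s) {
  if (!is.finite(tau_m) || !is.finite(tau_s) || tau_s <= 0 || tau_m <= tau_s) {
    stop("invalid parameters: need tau_m > tau_s > 0")
  }
  beta <- tau_m / tau_s
  beta^(beta / (beta - 1)) / (beta - 1)
}

#' LIF neuron parameters
#'
#' Bundles the time constants, firing threshold and grid step of the
#' current-based leaky integrate-and-fire neuron, together with the
#' derived kernel normalization [v_norm()].
#'
#' @param tau_m membrane time constant (ms).
#' @param tau_s synaptic time constant (ms).
#' @param theta firing threshold (mV).
#' @param dt simulation grid step (ms).
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 10, tau_s = 2.5, theta = 1, dt = 1) {
  if (theta <= 0) stop("invalid parameters: theta must be positive")
  if (dt <= 0) stop("invalid parameters: dt must be positive")
  structure(
    list(tau_m = tau_m, tau_s = tau_s, theta = theta, dt = dt,
         v_norm = v_norm(tau_m, tau_s)),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "LIF neuron: tau_m = %g ms, tau_s = %g ms, theta = %g mV, dt = %g ms (v_norm = %.5f)\n",
    x$tau_m, x$tau_s, x$theta, x$dt, x$v_norm))
  invisible(x)
}

#' Postsynaptic potential kernel
#'
#' Unit-peak double-exponential kernel
#' \eqn{K(x) = V_{norm} (e^{-x/\tau_m} - e^{-x/\tau_s})} for `x >= 0`,
#' and 0 for `x < 0` (causality). The peak value 1 is reached at
#' \eqn{x^* = \tau_m \tau_s / (\tau_m - \tau_s) \log(\tau_m/\tau_s)}.
#'
#' @param x elapsed time since the presynaptic spike (ms); vectorized.
#' @param params a [neuron_params()] object.
#' @return kernel values, same length as `x`.
#' @export
psp_kernel <- function(x, params = neuron_params()) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- params$v_norm *
    (exp(-x[pos] / params$tau_m) - exp(-x[pos] / params$tau_s))
  out
}
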