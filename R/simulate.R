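# Exponential-sum table for one time constant: entry (i, k) holds
# sum_{s < t_k} exp(-(t_k - s)/tau) over the spikes s of afferent i,
# built column by column with the one-step decay recurrence.
psp_exp_matrix <- function(pattern, tau, dt) {
  Tn <- time_col(pattern$duration, dt)
  N <- pattern$n_afferents
  cnt <- matrix(0, N, Tn)
  for (i in seq_len(N)) {
    s <- pattern$trains[[i]]
    if (length(s)) cnt[i, time_col(s, dt)] <- 1
  }
  E <- matrix(0, N, Tn)
  d <- exp(-dt / tau)
  if (Tn >= 2) {
    for (k in 2:Tn) E[, k] <- (E[, k - 1] + cnt[, k - 1]) * d
  }
  E
}

#' Precomputed PSP tables for a spike pattern
#'
#' Builds, once per pattern and parameter set, the per-afferent,
#' per-grid-time kernel sums that both simulation and all learning-rule
#' sums read from: `P[i, k] = sum_{s < t_k} K(t_k - s)` together with the
#' two exponential-sum tables (`Em`, `Es`, one per time constant) from
#' which `P` derives. Storage is `N * T/dt` entries per table.
#'
#' @param pattern a [spike_pattern()].
#' @param params a [neuron_params()].
#' @return list with matrices `P`, `Em`, `Es` (afferents by grid times,
#'   column `k` is time `(k-1)*dt`).
#' @export
psp_cache <- function(pattern, params = neuron_params()) {
  stopifnot(inherits(pattern, "spike_pattern"))
  if (abs(pattern$dt - params$dt) > 1e-12) {
    stop("pattern and neuron parameters use different grid steps")
  }
  Em <- psp_exp_matrix(pattern, params$tau_m, params$dt)
  Es <- psp_exp_matrix(pattern, params$tau_s, params$dt)
  list(P = params$v_norm * (Em - Es), Em = Em, Es = Es)
}

#' Per-afferent PSP table
#'
#' Convenience accessor for the summed-kernel table of [psp_cache()]:
#' entry `(i, k)` is the accumulated postsynaptic potential of afferent
#' `i` at grid time `(k-1)*dt` under unit weight.
#'
#' @inheritParams psp_cache
#' @return numeric matrix, `n_afferents` rows and `T/dt + 1` columns.
#' @export
psp_matrix <- function(pattern, params = neuron_params()) {
  psp_cache(pattern, params)$P
}

#' Simulate a LIF neuron on a spike pattern
#'
#' Iterates the time grid in order. At each step the membrane potential
#' is the weighted kernel sum over all earlier input spikes minus the
#' reset sum over earlier output spikes; when it reaches the threshold a
#' spike is recorded and the reset applies to all later steps. A spike at
#' time t influences the potential strictly after t only.
#'
#' @param pattern a [spike_pattern()].
#' @param weights numeric vector of synaptic strengths, one per afferent.
#' @param params a [neuron_params()].
#' @param stop_at optional time (ms): the scan halts after this grid
#'   time, leaving later potentials uncomputed.
#' @param voltage_noise_sd optional SD (mV) of i.i.d. zero-mean Gaussian
#'   noise added to the potential at every step before the threshold
#'   comparison (evaluation-time background noise).
#' @param cache optional precomputed [psp_cache()] for `pattern`.
#' @return an object of class `voltage_trace`: list with `values` (mV at
#'   each computed grid time), `times`, `output_spikes` (ms) and the
#'   parameters used.
#' @export
simulate_lif <- function(pattern, weights, params = neuron_params(),
                         stop_at = NULL, voltage_noise_sd = NULL,
                         cache = NULL) {
  stopifnot(inherits(pattern, "spike_pattern"))
  if (length(weights) != pattern$n_afferents) {
    stop("length(weights) must equal the number of afferents")
  }
  if (length(weights) && any(!is.finite(weights))) stop("non-finite weights")
  P <- (cache %||% psp_cache(pattern, params))$P
  u <- as.vector(matrix(weights, 1L) %*% P)
  Tn <- length(u)
  stop_idx <- -1L
  if (!is.null(stop_at)) {
    if (stop_at < 0 || stop_at > pattern$duration) {
      stop("stop_at outside [0, duration]")
    }
    stop_idx <- time_col(stop_at, params$dt)
  }
  noise <- if (is.null(voltage_noise_sd)) numeric(0) else {
    stats::rnorm(Tn, 0, voltage_noise_sd)
  }
  res <- .lif_scan(u, params$theta, exp(-params$dt / params$tau_m),
                   stop_idx, noise)
  structure(
    list(values = res$v,
         times = seq(0, by = params$dt, length.out = length(res$v)),
         output_spikes = (res$spike_idx - 1) * params$dt,
         params = params, duration = pattern$duration),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage trace: %d steps, %d output spikes\n",
              length(x$values), length(x$output_spikes)))
  invisible(x)
}
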