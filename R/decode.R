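#' Dynamic decoding configuration
#'
#' @param theta_e encoding threshold (mV), strictly between 0 and the
#'   firing threshold: a target neuron whose subthreshold peak stays
#'   below it receives no further increments.
#' @param margin optional multiplicative training margin: during
#'   training, spike detection for non-target neurons uses
#'   `theta * (1 - margin)` and target-neuron increments aim at
#'   `theta * (1 + margin)`. Disabled (0) by default.
#' @param group_count number of categories G.
#' @param neurons_per_group readout neurons per category M.
#' @param theta firing threshold (mV) the encoding threshold is compared
#'   against.
#' @return an object of class `dynamic_decode_config`.
#' @export
dynamic_decode_config <- function(theta_e = 0.6, margin = 0,
                                  group_count = 2, neurons_per_group = 10,
                                  theta = 1) {
  stopifnot(theta_e > 0, theta_e < theta, group_count >= 1,
            neurons_per_group >= 1, margin >= 0)
  structure(
    list(theta_e = theta_e, margin = margin, group_count = group_count,
         neurons_per_group = neurons_per_group, theta = theta),
    class = "dynamic_decode_config"
  )
}

#' Dynamically determine the target train for a readout neuron
#'
#' Builds, from one presentation's voltage trace, the desired spike
#' train and the single learning event of a readout neuron:
#' * non-target neuron, silent: no update;
#' * non-target neuron with output spikes: decrement at the first
#'   actual output spike time;
#' * target neuron, silent: desired train is the time of the
#'   subthreshold voltage maximum, increment there;
#' * target neuron with output spikes and subthreshold maximum above the
#'   encoding threshold: desired train is the actual output plus that
#'   maximum time, increment there;
#' * target neuron with output spikes and subthreshold maximum at or
#'   below the encoding threshold: desired train is the actual output,
#'   no update.
#'
#' The subthreshold maximum is taken over grid steps at which no spike
#' fired; ties resolve to the earliest such time.
#'
#' @param is_target whether the neuron's group matches the sample label.
#' @param trace a [simulate_lif()] voltage trace of the presentation.
#' @param config a [dynamic_decode_config()].
#' @return list with `desired` (spike train), `t_err` (time of the
#'   scheduled update or `NULL`), and `update` (`"increment"`,
#'   `"decrement"` or `NULL`).
#' @export
dynamic_targets <- function(is_target, trace, config) {
  stopifnot(inherits(trace, "voltage_trace"))
  to <- trace$output_spikes
  if (!is_target) {
    if (!length(to)) {
      return(list(desired = numeric(0), t_err = NULL, update = NULL))
    }
    return(list(desired = numeric(0), t_err = to[1], update = "decrement"))
  }
  free <- trace$values
  if (length(to)) free[time_col(to, trace$params$dt)] <- -Inf
  if (all(!is.finite(free))) {
    # every step spiked: nothing subthreshold to aim at
    return(list(desired = to, t_err = NULL, update = NULL))
  }
  i_max <- which.max(free)
  t_max <- trace$times[i_max]
  v_max <- free[i_max]
  if (!length(to)) {
    return(list(desired = t_max, t_err = t_max, update = "increment"))
  }
  if (v_max > config$theta_e) {
    list(desired = sort(unique(c(to, t_max))), t_err = t_max,
         update = "increment")
  } else {
    list(desired = to, t_err = NULL, update = NULL)
  }
}

#' Population readout over groups of spike-count neurons
#'
#' Given the spike counts of a `G x M` array of readout neurons (one row
#' per category group, `M` neurons per group), the neuron with the
#' strictly largest count at each index position is "activated" (a tie
#' at an index activates no one). The predicted group has the most
#' activated neurons; global ties resolve to the largest total spike
#' count, then to the lowest group index.
#'
#' @param counts numeric `G x M` matrix of output spike counts.
#' @return an object of class `readout`: `counts`, per-group `activated`
#'   tallies, and `predicted_group`.
#' @export
population_predict <- function(counts) {
  counts <- as.matrix(counts)
  G <- nrow(counts)
  activated <- integer(G)
  for (m in seq_len(ncol(counts))) {
    col <- counts[, m]
    mx <- max(col)
    if (sum(col == mx) == 1L) {
      g <- which.max(col)
      activated[g] <- activated[g] + 1L
    }
  }
  cand <- which(activated == max(activated))
  if (length(cand) > 1L) {
    tot <- rowSums(counts)[cand]
    cand <- cand[tot == max(tot)]
  }
  structure(
    list(counts = counts, activated = activated,
         predicted_group = cand[1]),
    class = "readout"
  )
}

#' @export
print.readout <- function(x, ...) {
  cat(sprintf("population readout: predicted group %d (activated: %s)\n",
              x$predicted_group, paste(x$activated, collapse = ", ")))
  invisible(x)
}

#' Train a dynamically decoded readout population
#'
#' Trains `G x M` first-error readout neurons on a classification
#' dataset using dynamic target determination: per presentation each
#' neuron's voltage trace yields (via [dynamic_targets()]) at most one
#' increment or decrement. Prediction counts output spikes per neuron
#' and applies [population_predict()].
#'
#' @param dataset a [make_classification_dataset()] object (the class
#'   templates are ignored; targets are dynamic).
#' @param config a [learn_config()] (learning rates, initialization).
#' @param decode a [dynamic_decode_config()]; its `group_count` must
#'   equal the dataset's class count.
#' @param params a [neuron_params()].
#' @param epochs passes over the training set.
#' @return an object of class `dynamic_population` holding the
#'   `(G*M) x N` weight matrix and settings.
#' @export
fit_dynamic_population <- function(dataset, config = learn_config(),
                                   decode = dynamic_decode_config(),
                                   params = neuron_params(), epochs = 20) {
  stopifnot(inherits(dataset, "classification_dataset"),
            decode$group_count == dataset$n_classes)
  G <- decode$group_count
  M <- decode$neurons_per_group
  pats <- dataset$train$patterns
  labels <- dataset$train$labels
  N <- pats[[1]]$n_afferents
  caches <- lapply(pats, psp_cache, params = params)
  W <- t(vapply(seq_len(G * M), function(k) {
    with_seed(subseed(config$seed, 880000L + k),
              stats::rnorm(N, config$init_mean, config$init_sd))
  }, numeric(N)))

  # Optional training margin: detection thresholds shifted away from the
  # firing threshold during training only.
  par_lo <- par_hi <- params
  if (decode$margin > 0) {
    par_lo$theta <- params$theta * (1 - decode$margin)
    par_hi$theta <- params$theta * (1 + decode$margin)
  }

  for (ep in seq_len(epochs)) {
    for (s in seq_along(pats)) {
      for (k in seq_len(G * M)) {
        grp <- (k - 1L) %/% M + 1L
        is_target <- grp == labels[s]
        trace <- simulate_lif(pats[[s]], W[k, ],
                              if (is_target) par_hi else par_lo,
                              cache = caches[[s]])
        act <- dynamic_targets(is_target, trace, decode)
        if (is.null(act$update)) next
        if (act$update == "increment") {
          db <- act$desired[act$desired < act$t_err]
          W[k, ] <- W[k, ] + weight_increment(
            pats[[s]], W[k, ], db, act$t_err, config, params,
            cache = caches[[s]])
        } else {
          W[k, ] <- W[k, ] + weight_decrement(
            pats[[s]], act$t_err, config, params, cache = caches[[s]])
        }
      }
    }
  }
  structure(
    list(weights = W, decode = decode, config = config, params = params,
         duration = dataset$duration),
    class = "dynamic_population"
  )
}

#' Predict classes with a dynamically decoded population
#'
#' @param object a [fit_dynamic_population()] model.
#' @param patterns list of [spike_pattern()]s.
#' @param ... unused.
#' @return integer vector of predicted group indices.
#' @export
predict.dynamic_population <- function(object, patterns, ...) {
  G <- object$decode$group_count
  M <- object$decode$neurons_per_group
  vapply(patterns, function(pat) {
    cache <- psp_cache(pat, object$params)
    counts <- matrix(0L, G, M)
    for (k in seq_len(G * M)) {
      trace <- simulate_lif(pat, object$weights[k, ], object$params,
                            cache = cache)
      counts[(k - 1L) %/% M + 1L, (k - 1L) %% M + 1L] <-
        length(trace$output_spikes)
    }
    population_predict(counts)$predicted_group
  }, 0L)
}
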