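#' Classify a spike train by template matching
#'
#' Returns the index of the class template whose correlation metric with
#' the actual train is largest; ties resolve to the lowest class index
#' (an empty actual train scores 0 against every nonempty template and
#' therefore maps to class 1).
#'
#' @param actual numeric output spike train (ms).
#' @param templates list of per-class desired spike trains.
#' @param sigma Gaussian filter width (ms) of the metric.
#' @param duration signal duration (ms).
#' @param dt grid step (ms).
#' @return integer class index in `1..length(templates)`.
#' @export
classify_by_template <- function(actual, templates, sigma = 2, duration,
                                 dt = 1) {
  stopifnot(length(templates) >= 1)
  scores <- vapply(templates, function(tpl) {
    correlation_c(actual, tpl, sigma, duration, dt)
  }, 0.0)
  which.max(scores)
}

#' Train first-error template classifiers on a classification dataset
#'
#' One LIF neuron per class is trained with the first-error rule to emit
#' its class's desired output template in response to the jittered
#' training samples of that class: each epoch presents every own-class
#' sample once, applying at most one weight update (increment at a
#' missed tolerance window, decrement at a stray or duplicate spike) per
#' presentation. A pattern is classified into the class whose neuron's
#' output train is most similar to that class's template.
#'
#' @param dataset a [make_classification_dataset()] object.
#' @param config a [learn_config()]; `epsilon` sets the tolerance window
#'   width used in training and `seed` drives weight initialization.
#' @param params a [neuron_params()].
#' @param epochs passes over the training set.
#' @return an object of class `pattern_classifier` holding the
#'   `n_classes x n_afferents` weight matrix, templates and settings.
#' @export
fit_pattern_classifier <- function(dataset, config = learn_config(epsilon = 7),
                                   params = neuron_params(), epochs = 300) {
  stopifnot(inherits(dataset, "classification_dataset"))
  G <- dataset$n_classes
  pats <- dataset$train$patterns
  labels <- dataset$train$labels
  N <- pats[[1]]$n_afferents
  dt <- params$dt
  dm <- exp(-dt / params$tau_m)

  caches <- lapply(pats, psp_cache, params = params)
  windows <- lapply(dataset$templates, tolerance_windows,
                    epsilon = config$epsilon, dt = dt)
  W <- t(vapply(seq_len(G), function(cl) {
    with_seed(subseed(config$seed, 770000L + cl),
              stats::rnorm(N, config$init_mean, config$init_sd))
  }, numeric(N)))

  for (ep in seq_len(epochs)) {
    for (s in seq_along(pats)) {
      cl <- labels[s]
      cache <- caches[[s]]
      u <- as.vector(matrix(W[cl, ], 1L) %*% cache$P)
      res <- .lif_scan(u, params$theta, dm, -1L, numeric(0))
      actual <- (res$spike_idx - 1) * dt
      desired <- dataset$templates[[cl]]
      err <- find_first_error(actual, desired, config$epsilon, dt,
                              windows = windows[[cl]])
      if (is.null(err)) next
      if (err$kind == "c") {
        W[cl, ] <- W[cl, ] + weight_increment(
          pats[[s]], W[cl, ], desired[desired < err$t_err], err$t_err,
          config, params, cache = cache)
      } else {
        W[cl, ] <- W[cl, ] + weight_decrement(
          pats[[s]], err$t_err, config, params, cache = cache)
      }
    }
  }
  structure(
    list(weights = W, templates = dataset$templates, config = config,
         params = params, duration = dataset$duration, epochs = epochs),
    class = "pattern_classifier"
  )
}

#' Predict classes for spike patterns with a trained classifier
#'
#' Each class neuron is simulated on the input pattern and scored by the
#' correlation metric between its output train and its own class
#' template; the predicted class maximizes that score (ties resolve to
#' the lowest class index).
#'
#' @param object a [fit_pattern_classifier()] model.
#' @param patterns list of [spike_pattern()]s.
#' @param ... unused.
#' @return integer vector of predicted class indices.
#' @export
predict.pattern_classifier <- function(object, patterns, ...) {
  params <- object$params
  dt <- params$dt
  dm <- exp(-dt / params$tau_m)
  sig <- object$config$sigma_c
  vapply(patterns, function(pat) {
    cache <- psp_cache(pat, params)
    U <- object$weights %*% cache$P
    scores <- vapply(seq_len(nrow(U)), function(cl) {
      res <- .lif_scan(U[cl, ], params$theta, dm, -1L, numeric(0))
      correlation_c((res$spike_idx - 1) * dt, object$templates[[cl]],
                    sig, object$duration, dt)
    }, 0.0)
    which.max(scores)
  }, 0L)
}

#' Classification accuracy of a trained classifier
#'
#' @param object a [fit_pattern_classifier()] model.
#' @param set a list with `patterns` and `labels` (e.g. the `train` or
#'   `test` component of a [make_classification_dataset()]).
#' @return fraction of correctly classified samples.
#' @export
classifier_accuracy <- function(object, set) {
  mean(predict(object, set$patterns) == set$labels)
}
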