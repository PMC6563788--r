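#' Homogeneous Poisson spike train on the time grid
#'
#' Bernoulli-per-bin discretization of a homogeneous Poisson process:
#' each of the `duration/dt` grid bins independently holds a spike with
#' probability `rate * dt / 1000` (at most one spike per bin). A fixed
#' seed gives an identical train.
#'
#' @param rate firing rate (Hz), `>= 0`; `rate * dt / 1000` must not
#'   exceed 1.
#' @param duration train duration (ms).
#' @param dt grid step (ms).
#' @param seed RNG seed (`NULL` uses the ambient RNG stream).
#' @param t_min first candidate bin time (ms, in `[0, dt]`); the bins are
#'   `t_min, t_min + dt, ...` spanning `duration/dt` steps. Target-train
#'   generation uses `t_min = dt` so that no desired spike sits at time
#'   0, where a spike can never be emitted.
#' @param min_gap minimum inter-spike interval (ms): spikes closer than
#'   this to the previously kept spike are rejected, so that tolerance
#'   windows of width `min_gap/dt` grid steps stay disjoint.
#' @return sorted numeric spike times (ms).
#' @export
poisson_train <- function(rate, duration, dt = 1, seed = NULL, t_min = 0,
                          min_gap = 0) {
  stopifnot(rate >= 0, duration > 0, t_min >= 0, t_min <= dt)
  p <- rate * dt / 1000
  if (p > 1) stop("rate * dt / 1000 exceeds 1: grid too coarse for this rate")
  nb <- as.integer(round(duration / dt))
  times <- with_seed(seed, {
    hits <- stats::runif(nb) < p
    t_min + dt * (which(hits) - 1)
  })
  if (min_gap > 0 && length(times) > 1) {
    keep <- times[1]
    last <- times[1]
    for (t in times[-1]) {
      if (t - last >= min_gap) {
        keep <- c(keep, t)
        last <- t
      }
    }
    times <- keep
  }
  times
}

#' Multi-afferent homogeneous Poisson pattern
#'
#' Draws `n_afferents` independent [poisson_train()]s. Each afferent uses
#' a sub-seed derived from `seed` and the afferent index only, so the
#' train of afferent `i` does not depend on `n_afferents`.
#'
#' @param n_afferents number of afferents.
#' @inheritParams poisson_train
#' @return a [spike_pattern()].
#' @export
poisson_pattern <- function(n_afferents, rate, duration, dt = 1,
                            seed = NULL) {
  trains <- lapply(seq_len(n_afferents), function(i) {
    poisson_train(rate, duration, dt, seed = subseed(seed, i))
  })
  spike_pattern(trains, duration = duration, dt = dt)
}

#' Jitter-noise specification
#'
#' @param sigma_j SD (ms) of the zero-mean Gaussian jitter added to each
#'   surviving input spike.
#' @param p_delete per-spike deletion probability in `[0, 1]`.
#' @param add_rate rate (Hz) of the homogeneous Poisson process whose
#'   spikes are merged into each afferent.
#' @return an object of class `jitter_spec`.
#' @export
jitter_spec <- function(sigma_j = 0, p_delete = 0, add_rate = 0) {
  stopifnot(sigma_j >= 0, p_delete >= 0, p_delete <= 1, add_rate >= 0)
  structure(list(sigma_j = sigma_j, p_delete = p_delete,
                 add_rate = add_rate), class = "jitter_spec")
}

#' Perturb a spike pattern with jitter, deletion and insertion noise
#'
#' Per afferent: each original spike is deleted independently with
#' probability `p_delete`; each survivor is shifted by an independent
#' Gaussian draw (SD `sigma_j`), rounded to the grid and clipped to
#' `[0, duration]`; an independent Poisson train at `add_rate` is merged
#' in. Trains are re-sorted and spikes colliding on the same grid point
#' merge into one.
#'
#' @param pattern a [spike_pattern()].
#' @param spec a [jitter_spec()].
#' @param seed RNG seed (`NULL` uses the ambient RNG stream).
#' @return a perturbed [spike_pattern()].
#' @export
jitter_pattern <- function(pattern, spec, seed = NULL) {
  stopifnot(inherits(pattern, "spike_pattern"), inherits(spec, "jitter_spec"))
  dt <- pattern$dt
  dur <- pattern$duration
  trains <- with_seed(seed, {
    lapply(pattern$trains, function(s) {
      if (length(s) && spec$p_delete > 0) {
        s <- s[stats::runif(length(s)) >= spec$p_delete]
      }
      if (length(s) && spec$sigma_j > 0) {
        s <- round((s + stats::rnorm(length(s), 0, spec$sigma_j)) / dt) * dt
        s <- pmin(pmax(s, 0), dur)
      }
      if (spec$add_rate > 0) {
        s <- c(s, poisson_train(spec$add_rate, dur, dt))
      }
      sort(unique(s))
    })
  })
  spike_pattern(trains, duration = dur, dt = dt)
}

#' Synthetic multi-class spatiotemporal classification dataset
#'
#' Draws one base Poisson pattern per class, then derives training and
#' test samples by Gaussian-jittering every spike of the base pattern
#' (no deletions or insertions). Each class has a fixed desired output
#' template; the defaults are the three interleaved arithmetic sequences
#' 5:15:170, 15:15:180 and 25:15:190 ms.
#'
#' @param n_classes number of classes.
#' @param n_afferents afferents per pattern.
#' @param base_rate Poisson rate (Hz) of the base patterns.
#' @param duration pattern duration (ms).
#' @param n_train,n_test samples per class.
#' @param jitter_sd SD (ms) of the sample jitter.
#' @param templates list of desired spike trains, one per class
#'   (required when `n_classes != 3`).
#' @param dt grid step (ms).
#' @param seed RNG seed driving every draw.
#' @return an object of class `classification_dataset`: `classes` (base
#'   patterns), `templates`, and `train` / `test` lists each holding
#'   `patterns` and integer `labels`.
#' @export
make_classification_dataset <- function(n_classes = 3, n_afferents = 400,
                                        base_rate = 5, duration = 200,
                                        n_train = 25, n_test = 25,
                                        jitter_sd = 3, templates = NULL,
                                        dt = 1, seed = NULL) {
  if (is.null(templates)) {
    if (n_classes != 3) stop("templates must be given when n_classes != 3")
    templates <- list(seq(5, 170, by = 15), seq(15, 180, by = 15),
                      seq(25, 190, by = 15))
  }
  if (length(templates) != n_classes) {
    stop("need one template per class")
  }
  for (tpl in templates) check_times(tpl, duration, dt, "template")
  bases <- lapply(seq_len(n_classes), function(cl) {
    poisson_pattern(n_afferents, base_rate, duration, dt,
                    seed = subseed(seed, 900000L + cl))
  })
  spec <- jitter_spec(sigma_j = jitter_sd)
  draw_set <- function(tag, n_per) {
    pats <- vector("list", n_classes * n_per)
    labels <- integer(n_classes * n_per)
    k <- 0L
    for (cl in seq_len(n_classes)) {
      for (r in seq_len(n_per)) {
        k <- k + 1L
        pats[[k]] <- jitter_pattern(bases[[cl]], spec,
                                    seed = subseed(seed, tag + cl * 1000L + r))
        labels[k] <- cl
      }
    }
    list(patterns = pats, labels = labels)
  }
  structure(
    list(classes = bases, templates = templates,
         train = draw_set(100000L, n_train),
         test = draw_set(200000L, n_test),
         duration = duration, dt = dt, n_classes = n_classes),
    class = "classification_dataset"
  )
}

#' @export
print.classification_dataset <- function(x, ...) {
  cat(sprintf(
    "classification dataset: %d classes, %d train / %d test samples, %g ms\n",
    x$n_classes, length(x$train$labels), length(x$test$labels), x$duration))
  invisible(x)
}
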