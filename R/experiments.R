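#' One single-neuron learning trial on Poisson input
#'
#' Draws a fresh Poisson input pattern and a Poisson target train (the
#' target avoids time 0 and enforces a minimum inter-spike gap of
#' `epsilon * dt` so tolerance windows stay disjoint), then trains a
#' neuron with the first-error rule.
#'
#' @param n_afferents number of input afferents.
#' @param duration trial duration (ms).
#' @param rate_in input firing rate (Hz).
#' @param rate_out desired output firing rate (Hz).
#' @param config a [learn_config()]; its `seed` is replaced by a
#'   sub-seed derived from `seed`.
#' @param params a [neuron_params()].
#' @param seed trial seed driving pattern, target and weight draws.
#' @return the [fe_train()] record, with the pattern and target attached
#'   as attributes `pattern` and `desired`.
#' @export
learning_trial <- function(n_afferents = 400, duration = 800,
                           rate_in = 10, rate_out = 100,
                           config = learn_config(),
                           params = neuron_params(), seed = 1) {
  pattern <- poisson_pattern(n_afferents, rate_in, duration, params$dt,
                             seed = subseed(seed, 11))
  desired <- poisson_train(rate_out, duration, params$dt,
                           seed = subseed(seed, 22), t_min = params$dt,
                           min_gap = config$epsilon * params$dt)
  config$seed <- subseed(seed, 33)
  rec <- fe_train(pattern, desired, config, params)
  attr(rec, "pattern") <- pattern
  attr(rec, "desired") <- desired
  rec
}

trial_row <- function(rec, ...) {
  data.frame(..., best_c = rec$best_c, best_epoch = rec$best_epoch,
             converged = rec$converged,
             epochs = length(rec$c_history) - 1L)
}

exp_duration_sweep <- function(durations = c(400, 800, 1600, 2200),
                               trials = 5, n_afferents = 400,
                               rate_in = 10, rate_out = 100,
                               config = learn_config(max_epochs = 30000),
                               params = neuron_params(), seed = 1) {
  eps_for <- function(d) if (d <= 1000) 1 else if (d <= 2000) 3 else 5
  do.call(rbind, lapply(durations, function(d) {
    cfg <- config
    cfg$epsilon <- eps_for(d)
    do.call(rbind, lapply(seq_len(trials), function(k) {
      rec <- learning_trial(n_afferents, d, rate_in, rate_out, cfg, params,
                            seed = subseed(seed, d * 100 + k))
      trial_row(rec, duration = d, epsilon = cfg$epsilon, trial = k)
    }))
  }))
}

exp_afferent_sweep <- function(n_grid = c(100, 200, 400), trials = 5,
                               duration = 800, rate_in = 10, rate_out = 100,
                               config = learn_config(max_epochs = 30000),
                               params = neuron_params(), seed = 1) {
  eps_for <- function(n) if (n < 150) 5 else if (n < 300) 3 else 1
  do.call(rbind, lapply(n_grid, function(n) {
    cfg <- config
    cfg$epsilon <- eps_for(n)
    do.call(rbind, lapply(seq_len(trials), function(k) {
      rec <- learning_trial(n, duration, rate_in, rate_out, cfg, params,
                            seed = subseed(seed, n * 100 + k))
      trial_row(rec, n_afferents = n, epsilon = cfg$epsilon, trial = k)
    }))
  }))
}

exp_rate_grid <- function(rates_in = c(6, 10, 18), rates_out = c(20, 100, 160),
                          trials = 5, duration = 800, n_afferents = 400,
                          config = learn_config(max_epochs = 30000),
                          params = neuron_params(), seed = 1) {
  grid <- expand.grid(rate_in = rates_in, rate_out = rates_out)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    rin <- grid$rate_in[g]; rout <- grid$rate_out[g]
    do.call(rbind, lapply(seq_len(trials), function(k) {
      rec <- learning_trial(n_afferents, duration, rin, rout, config,
                            params, seed = subseed(seed, g * 1000 + k))
      trial_row(rec, rate_in = rin, rate_out = rout, trial = k)
    }))
  }))
}

# Train once per trial, then re-simulate under evaluation-time noise and
# measure the correlation metric against the target train.
exp_background_noise <- function(sigma_b = c(0.03, 0.15, 0.33), trials = 3,
                                 n_eval = 20, duration = 500,
                                 n_afferents = 400, rate_in = 10,
                                 rate_out = 100,
                                 config = learn_config(max_epochs = 30000),
                                 params = neuron_params(), seed = 1) {
  do.call(rbind, lapply(seq_len(trials), function(k) {
    rec <- learning_trial(n_afferents, duration, rate_in, rate_out, config,
                          params, seed = subseed(seed, 5000 + k))
    pattern <- attr(rec, "pattern"); desired <- attr(rec, "desired")
    cache <- psp_cache(pattern, params)
    do.call(rbind, lapply(sigma_b, function(sb) {
      cs <- with_seed(subseed(seed, 6000 + k), vapply(seq_len(n_eval), function(e) {
        tr <- simulate_lif(pattern, rec$weights, params,
                           voltage_noise_sd = sb, cache = cache)
        correlation_c(tr$output_spikes, desired, config$sigma_c,
                      duration, params$dt)
      }, 0.0))
      data.frame(sigma_b = sb, trial = k, mean_c = mean(cs))
    }))
  }))
}

exp_jitter_noise <- function(sigma_j = c(0.2, 1, 2), trials = 3,
                             n_eval = 20, duration = 500,
                             n_afferents = 400, rate_in = 10,
                             rate_out = 100, p_delete = 0.05, add_rate = 1,
                             config = learn_config(max_epochs = 30000),
                             params = neuron_params(), seed = 1) {
  do.call(rbind, lapply(seq_len(trials), function(k) {
    rec <- learning_trial(n_afferents, duration, rate_in, rate_out, config,
                          params, seed = subseed(seed, 7000 + k))
    pattern <- attr(rec, "pattern"); desired <- attr(rec, "desired")
    do.call(rbind, lapply(sigma_j, function(sj) {
      spec <- jitter_spec(sigma_j = sj, p_delete = p_delete,
                          add_rate = add_rate)
      cs <- vapply(seq_len(n_eval), function(e) {
        noisy <- jitter_pattern(pattern, spec,
                                seed = subseed(seed, 8000 + k * 100 + e))
        tr <- simulate_lif(noisy, rec$weights, params)
        correlation_c(tr$output_spikes, desired, config$sigma_c,
                      duration, params$dt)
      }, 0.0)
      data.frame(sigma_j = sj, trial = k, mean_c = mean(cs))
    }))
  }))
}

exp_eps_sr_sweep <- function(eps_values = c(1, 3, 5, 7),
                             sr_values = c(0, 1, 2), trials = 3,
                             duration = 800, n_afferents = 400,
                             rate_in = 10, rate_out = 100,
                             config = learn_config(max_epochs = 30000),
                             params = neuron_params(), seed = 1) {
  grid <- expand.grid(epsilon = eps_values, s_r = sr_values)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$epsilon <- grid$epsilon[g]
    cfg$s_r <- grid$s_r[g]
    do.call(rbind, lapply(seq_len(trials), function(k) {
      rec <- learning_trial(n_afferents, duration, rate_in, rate_out, cfg,
                            params, seed = subseed(seed, g * 1000 + k))
      trial_row(rec, epsilon = cfg$epsilon, s_r = cfg$s_r, trial = k)
    }))
  }))
}

exp_classification <- function(seeds = 1:5, epsilon = 7, epochs = 300,
                               config = learn_config(epsilon = epsilon),
                               params = neuron_params(), ...) {
  config$epsilon <- epsilon
  do.call(rbind, lapply(seeds, function(sd) {
    dataset <- make_classification_dataset(seed = sd, ...)
    config$seed <- subseed(sd, 44)
    model <- fit_pattern_classifier(dataset, config, params,
                                    epochs = epochs)
    data.frame(seed = sd, epsilon = epsilon,
               train_accuracy = classifier_accuracy(model, dataset$train),
               test_accuracy = classifier_accuracy(model, dataset$test))
  }))
}

exp_overfit_sweep <- function(eps_values = c(1, 7, 9), seeds = 1:5,
                              epochs = 300, params = neuron_params(), ...) {
  do.call(rbind, lapply(eps_values, function(eps) {
    exp_classification(seeds = seeds, epsilon = eps, epochs = epochs,
                       params = params, ...)
  }))
}

#' Run a named experiment protocol
#'
#' Dispatches to one of the built-in experiment protocols with reduced
#' default grids and trial counts; every knob can be overridden through
#' `...`. Per-trial results are returned as a data frame and, when
#' `out_dir` is given, written as `<name>.csv` alongside a JSON summary
#' of the aggregate means.
#'
#' @param name one of `"duration_sweep"`, `"afferent_sweep"`,
#'   `"rate_grid"`, `"background_noise"`, `"jitter_noise"`,
#'   `"eps_sr_sweep"`, `"overfit_sweep"`, `"classification"`.
#' @param ... overrides passed to the protocol function.
#' @param out_dir optional output directory.
#' @return data frame of per-trial results.
#' @export
run_experiment <- function(name, ..., out_dir = NULL) {
  fn <- switch(name,
    duration_sweep = exp_duration_sweep,
    afferent_sweep = exp_afferent_sweep,
    rate_grid = exp_rate_grid,
    background_noise = exp_background_noise,
    jitter_noise = exp_jitter_noise,
    eps_sr_sweep = exp_eps_sr_sweep,
    overfit_sweep = exp_overfit_sweep,
    classification = exp_classification,
    stop("unknown experiment: ", name)
  )
  res <- fn(...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE, quote = FALSE)
    num <- vapply(res, is.numeric, TRUE)
    jsonlite::write_json(as.list(colMeans(res[num])),
                         file.path(out_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
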