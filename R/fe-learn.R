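#' Learning configuration for the first-error rule
#'
#' @param epsilon tolerance window width in grid steps; must be odd. The
#'   window around each desired spike has half-width `(epsilon-1)/2 * dt`,
#'   so `epsilon = 1` demands exact spike times.
#' @param s_r scaling rate (>= 0) applied to the chain-rule contributions
#'   of desired spike times earlier than the error time in a weight
#'   increment.
#' @param lambda1 increment learning rate (> 0).
#' @param lambda2 decrement learning rate (> 0).
#' @param max_epochs epoch budget for [fe_train()].
#' @param seed RNG seed for weight initialization (`NULL` for ambient RNG).
#' @param init_mean,init_sd Gaussian weight initialization parameters.
#'   The default SD 0.1 reads the conventional N(0.01, 0.01) notation as
#'   mean and variance; pass `init_sd = 0.01` for the SD reading.
#' @param sigma_c Gaussian filter width (ms) of the correlation metric
#'   recorded per epoch.
#' @return an object of class `learn_config`.
#' @export
learn_config <- function(epsilon = 1, s_r = 1, lambda1 = 0.005,
                         lambda2 = 0.005, max_epochs = 10000, seed = NULL,
                         init_mean = 0.01, init_sd = 0.1, sigma_c = 2) {
  if (epsilon < 1 || epsilon %% 2 != 1) {
    stop("epsilon must be a positive odd number of grid steps")
  }
  if (s_r < 0) stop("s_r must be nonnegative")
  if (lambda1 <= 0 || lambda2 <= 0) stop("learning rates must be positive")
  if (max_epochs < 1) stop("max_epochs must be positive")
  structure(
    list(epsilon = epsilon, s_r = s_r, lambda1 = lambda1, lambda2 = lambda2,
         max_epochs = as.integer(max_epochs), seed = seed,
         init_mean = init_mean, init_sd = init_sd, sigma_c = sigma_c),
    class = "learn_config"
  )
}

#' Tolerance windows around desired spike times
#'
#' Window `j` is the closed interval centred on the j-th desired time
#' with half-width `(epsilon - 1)/2 * dt`. Windows must be pairwise
#' disjoint; an error is raised otherwise.
#'
#' @param desired numeric desired spike times (ms), strictly increasing.
#' @param epsilon window width in grid steps (odd).
#' @param dt grid step (ms).
#' @return two-column matrix `lo`, `hi`, one row per desired spike.
#' @export
tolerance_windows <- function(desired, epsilon, dt = 1) {
  if (epsilon < 1 || epsilon %% 2 != 1) {
    stop("epsilon must be a positive odd number of grid steps")
  }
  desired <- sort(as.numeric(desired))
  h <- (epsilon - 1) / 2 * dt
  w <- cbind(lo = desired - h, hi = desired + h)
  if (length(desired) > 1 && any(w[-1, "lo"] <= w[-nrow(w), "hi"])) {
    stop("overlapping tolerance windows: desired spikes closer than epsilon allows")
  }
  w
}

error_event <- function(t_err, kind) {
  structure(list(t_err = t_err, kind = kind), class = "error_event")
}

#' @export
print.error_event <- function(x, ...) {
  cat(sprintf("first error: type %s at t = %g ms\n", x$kind, x$t_err))
  invisible(x)
}

#' First wrong output spike time
#'
#' Scans time forward, matching actual output spikes to the tolerance
#' windows of the desired train in chronological order; each window
#' accepts at most its first in-window spike. The earliest violation is
#' reported:
#' * type `a` — a spike outside every window (error at the spike time);
#' * type `b` — a second spike inside an already-matched window (error at
#'   that spike time);
#' * type `c` — a window whose upper edge passes with no matched spike
#'   (error at the desired spike time itself).
#'
#' When a stray spike coincides with the closing edge of an unfilled
#' window at the same grid time, type `c` takes precedence. Returns
#' `NULL` iff every window matched exactly once and no stray spikes
#' exist.
#'
#' @param actual numeric actual output spike times (ms).
#' @param desired numeric desired spike times (ms).
#' @param epsilon window width in grid steps (odd).
#' @param dt grid step (ms).
#' @param windows optional precomputed [tolerance_windows()] matrix.
#' @return an `error_event` (fields `t_err`, `kind`) or `NULL`.
#' @export
find_first_error <- function(actual, desired, epsilon, dt = 1,
                             windows = NULL) {
  actual <- as.numeric(actual); desired <- sort(as.numeric(desired))
  if (!length(desired)) {
    if (!length(actual)) return(NULL)
    return(error_event(actual[1], "a"))
  }
  w <- windows %||% tolerance_windows(desired, epsilon, dt)
  lo <- w[, 1]; hi <- w[, 2]
  if (!length(actual)) return(error_event(desired[1], "c"))

  wi <- findInterval(actual, lo)
  inw <- wi >= 1L & actual <= hi[pmax(wi, 1L)]
  t_a <- if (any(!inw)) actual[!inw][1] else Inf
  win_in <- wi[inw]
  b_times <- actual[inw][duplicated(win_in)]
  t_b <- if (length(b_times)) b_times[1] else Inf
  unmatched <- setdiff(seq_along(desired), win_in)
  det_c <- if (length(unmatched)) hi[unmatched[1]] else Inf

  m <- min(t_a, t_b, det_c)
  if (is.infinite(m)) return(NULL)
  if (det_c <= m) return(error_event(desired[unmatched[1]], "c"))
  if (t_a <= t_b) error_event(t_a, "a") else error_event(t_b, "b")
}

#' Time derivative of the membrane potential at a spike time
#'
#' Left-sided derivative of the reset-inclusive potential at an output
#' spike time: a synaptic rise term over `tau_s`, a synaptic decay term
#' over `tau_m`, and a recovery term over `tau_m` from earlier output
#' spikes. Under the linear threshold-crossing assumption its negative
#' reciprocal gives the sensitivity of the spike time to the potential.
#'
#' @param t_spike the output spike time (ms).
#' @param pattern the input [spike_pattern()].
#' @param weights synaptic weights.
#' @param prior_output earlier output spike times (all `< t_spike`).
#' @param params a [neuron_params()].
#' @return derivative in mV per ms.
#' @export
voltage_time_derivative <- function(t_spike, pattern, weights,
                                    prior_output = numeric(0),
                                    params = neuron_params()) {
  stopifnot(inherits(pattern, "spike_pattern"))
  if (length(prior_output) && any(prior_output >= t_spike)) {
    stop("prior_output must contain only spikes earlier than t_spike")
  }
  es <- vapply(pattern$trains, function(s) {
    s <- s[s < t_spike]
    if (length(s)) sum(exp(-(t_spike - s) / params$tau_s)) else 0
  }, 0.0)
  em <- vapply(pattern$trains, function(s) {
    s <- s[s < t_spike]
    if (length(s)) sum(exp(-(t_spike - s) / params$tau_m)) else 0
  }, 0.0)
  val <- params$v_norm *
    (sum(weights * es) / params$tau_s - sum(weights * em) / params$tau_m)
  if (length(prior_output)) {
    val <- val + params$theta / params$tau_m *
      sum(exp(-(t_spike - prior_output) / params$tau_m))
  }
  val
}

# Slope below which a pinned crossing counts as degenerate and its
# chain-rule contribution is skipped. A genuine upward threshold crossing
# on the grid must gain order-theta potential within one step, so slopes
# far below theta/dt (and all non-positive slopes) indicate that the
# linear-crossing inversion is invalid there.
vdot_min <- function(params) 0.1 * params$theta / params$dt

#' Weight increment at a missed desired spike time (error type c)
#'
#' Gradient step that raises the membrane potential at the missed
#' desired time `t_err` toward the threshold. The update has a direct
#' term — the accumulated PSP of each afferent at `t_err` — plus, scaled
#' by `s_r`, one chain-rule term per desired spike time earlier than
#' `t_err`, in which every earlier actual output spike time is replaced
#' by its desired time. The iterative (recursive) part of the chain rule
#' is dropped. Contributions whose time derivative at the pinned spike
#' time falls below `0.1 * theta / dt` are skipped as degenerate
#' crossings (the pinned time is not a true threshold crossing there, so
#' the linearized inversion of the crossing is invalid).
#'
#' @param pattern input [spike_pattern()].
#' @param weights current synaptic weights.
#' @param desired_before desired spike times earlier than `t_err` (ms).
#' @param t_err the missed desired spike time (ms).
#' @param config a [learn_config()] (uses `lambda1`, `s_r`).
#' @param params a [neuron_params()].
#' @param cache optional [psp_cache()] for `pattern`.
#' @return per-afferent weight change, length `n_afferents`.
#' @export
weight_increment <- function(pattern, weights, desired_before, t_err,
                             config, params = neuron_params(),
                             cache = NULL) {
  cache <- cache %||% psp_cache(pattern, params)
  dt <- params$dt
  dw <- cache$P[, time_col(t_err, dt)]
  db <- sort(as.numeric(desired_before))
  if (config$s_r > 0 && length(db)) {
    kd <- time_col(db, dt)
    vdots <- as.vector(matrix(weights, 1L) %*%
      (params$v_norm * (cache$Es[, kd, drop = FALSE] / params$tau_s -
                          cache$Em[, kd, drop = FALSE] / params$tau_m)))
    vdots <- vdots + params$theta / params$tau_m * reset_recovery(db, params$tau_m)
    ok <- vdots >= vdot_min(params)
    if (any(ok)) {
      coefs <- (params$theta / params$tau_m) *
        exp(-(t_err - db[ok]) / params$tau_m) / vdots[ok]
      dw <- dw + config$s_r *
        as.vector(cache$P[, kd[ok], drop = FALSE] %*% coefs)
    }
  }
  config$lambda1 * dw
}

# reset_recovery(times, tau)[j] = sum_{k < j} exp(-(t_j - t_k)/tau),
# built with the interval recurrence r_j = (r_{j-1} + 1) * exp(-gap/tau).
reset_recovery <- function(times, tau) {
  m <- length(times)
  r <- numeric(m)
  if (m > 1) {
    d <- exp(-diff(times) / tau)
    for (j in 2:m) r[j] <- (r[j - 1] + 1) * d[j - 1]
  }
  r
}

#' Weight decrement at an undesired output spike time (error types a, b)
#'
#' Lowers the membrane potential at the stray spike time: the change of
#' each weight is minus `lambda2` times the accumulated PSP of that
#' afferent at `t_err`. No chain-rule terms enter (the scaling rate is
#' zero for decrements), so correctly placed earlier spikes are not
#' disturbed.
#'
#' @inheritParams weight_increment
#' @param t_err the undesired output spike time (ms).
#' @return per-afferent weight change, length `n_afferents`.
#' @export
weight_decrement <- function(pattern, t_err, config,
                             params = neuron_params(), cache = NULL) {
  cache <- cache %||% psp_cache(pattern, params)
  -config$lambda2 * cache$P[, time_col(t_err, params$dt)]
}

#' Train a LIF neuron with the first-error rule
#'
#' Initializes weights from a Gaussian, then repeats: simulate the
#' response to `pattern`, record the correlation metric against
#' `desired`, locate the first wrong output spike time, and apply exactly
#' one weight increment (missed window) or decrement (stray or duplicate
#' spike). Training stops when no error remains (convergence) or after
#' `max_epochs` updates; non-convergence is reported, not an error.
#'
#' @param pattern input [spike_pattern()].
#' @param desired desired output spike train (ms).
#' @param config a [learn_config()].
#' @param params a [neuron_params()].
#' @param weights optional initial weights (overrides the Gaussian init).
#' @param log_dir optional directory: writes `epochs.csv`
#'   (`epoch,C,error_type,t_err`), `weights.csv` (`afferent,weight`) and
#'   `result.json` (`converged, epochs, best_C, best_epoch`).
#' @return an object of class `fe_train_record`: `converged`,
#'   `epochs_to_converge` (`NA` if not converged), `best_c`, `best_epoch`,
#'   `c_history` (C before each update, plus the final state), `weights`,
#'   and `error_log` (data frame of per-epoch error type and time).
#' @export
fe_train <- function(pattern, desired, config = learn_config(),
                     params = neuron_params(), weights = NULL,
                     log_dir = NULL) {
  stopifnot(inherits(pattern, "spike_pattern"))
  desired <- sort(as.numeric(desired))
  check_times(desired, pattern$duration, params$dt, what = "desired train")
  windows <- tolerance_windows(desired, config$epsilon, params$dt)
  cache <- psp_cache(pattern, params)
  N <- pattern$n_afferents
  dt <- params$dt
  Tn <- ncol(cache$P)
  w <- weights %||%
    with_seed(config$seed, stats::rnorm(N, config$init_mean, config$init_sd))
  if (length(w) != N) stop("initial weights have wrong length")

  dm <- exp(-dt / params$tau_m)
  g <- exp(-((0:(Tn - 1)) * dt)^2 / (2 * config$sigma_c^2))
  vd <- if (length(desired)) .profile_sum(time_col(desired, dt), g, Tn) else numeric(Tn)
  vd2 <- sum(vd * vd)

  n_slots <- config$max_epochs + 1L
  c_hist <- numeric(n_slots)
  err_kind <- character(n_slots)
  err_time <- rep(NA_real_, n_slots)
  converged <- FALSE
  n_updates <- 0L

  for (ep in 0:config$max_epochs) {
    u <- as.vector(matrix(w, 1L) %*% cache$P)
    res <- .lif_scan(u, params$theta, dm, -1L, numeric(0))
    actual <- (res$spike_idx - 1) * dt
    cv <- if (!length(actual) && !length(desired)) 1
    else if (!length(actual) || !length(desired)) 0
    else {
      vo <- .profile_sum(res$spike_idx, g, Tn)
      min(max(sum(vo * vd) / sqrt(sum(vo * vo) * vd2), 0), 1)
    }
    c_hist[ep + 1L] <- cv
    err <- find_first_error(actual, desired, config$epsilon, dt,
                            windows = windows)
    if (is.null(err)) {
      converged <- TRUE
      break
    }
    err_kind[ep + 1L] <- err$kind
    err_time[ep + 1L] <- err$t_err
    if (ep == config$max_epochs) break
    if (err$kind == "c") {
      w <- w + weight_increment(pattern, w,
                                desired[desired < err$t_err], err$t_err,
                                config, params, cache = cache)
    } else {
      w <- w + weight_decrement(pattern, err$t_err, config, params,
                                cache = cache)
    }
    n_updates <- n_updates + 1L
  }

  n_seen <- n_updates + 1L
  c_hist <- c_hist[seq_len(n_seen)]
  best_epoch <- which.max(c_hist) - 1L
  rec <- structure(
    list(converged = converged,
         epochs_to_converge = if (converged) n_updates else NA_integer_,
         best_c = c_hist[best_epoch + 1L],
         best_epoch = best_epoch,
         c_history = c_hist,
         weights = w,
         error_log = data.frame(
           epoch = seq_len(n_seen) - 1L,
           C = c_hist,
           error_type = err_kind[seq_len(n_seen)],
           t_err = err_time[seq_len(n_seen)])),
    class = "fe_train_record"
  )
  if (!is.null(log_dir)) {
    dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rec$error_log, file.path(log_dir, "epochs.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(afferent = seq_len(N) - 1L, weight = w),
      file.path(log_dir, "weights.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(converged = rec$converged,
           epochs = if (rec$converged) rec$epochs_to_converge else NA,
           best_C = rec$best_c, best_epoch = rec$best_epoch),
      file.path(log_dir, "result.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  rec
}

#' @export
print.fe_train_record <- function(x, ...) {
  cat(sprintf("first-error training: %s after %d update(s); best C = %.4f at epoch %d\n",
              if (x$converged) "converged" else "not converged",
              length(x$c_history) - 1L, x$best_c, x$best_epoch))
  invisible(x)
}
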