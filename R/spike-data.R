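#' Spike train constructor
#'
#' A spike train is a strictly increasing numeric vector of spike times
#' (ms), each an integer multiple of the grid step `dt` inside
#' `[0, duration]`. Most functions in the package accept plain numeric
#' vectors; this constructor validates and normalizes.
#'
#' @param times numeric spike times (ms); sorted internally.
#' @param duration train duration T (ms).
#' @param dt grid step (ms).
#' @return sorted numeric vector of class `spike_train`.
#' @export
spike_train <- function(times = numeric(0), duration, dt = 1) {
  times <- sort(as.numeric(times))
  check_times(times, duration, dt)
  structure(times, class = "spike_train", duration = duration, dt = dt)
}

#' Multi-afferent spike pattern
#'
#' The input to one neuron: a list of `n_afferents` spike trains sharing
#' a common duration and grid step.
#'
#' @param trains list of numeric spike-time vectors, one per afferent.
#' @param duration common duration T (ms).
#' @param dt grid step (ms).
#' @return an object of class `spike_pattern`.
#' @export
spike_pattern <- function(trains, duration, dt = 1) {
  stopifnot(is.list(trains))
  trains <- lapply(seq_along(trains), function(i) {
    ti <- sort(as.numeric(trains[[i]]))
    check_times(ti, duration, dt, what = paste0("afferent ", i))
    ti
  })
  structure(
    list(trains = trains, duration = duration, n_afferents = length(trains),
         dt = dt),
    class = "spike_pattern"
  )
}

#' @export
print.spike_pattern <- function(x, ...) {
  cat(sprintf("spike pattern: %d afferents, %g ms at dt = %g ms, %d spikes\n",
              x$n_afferents, x$duration, x$dt,
              sum(lengths(x$trains))))
  invisible(x)
}

#' Write a spike pattern to CSV + JSON sidecar
#'
#' The CSV holds one row per spike with header `channel,time_ms`
#' (0-based channel); the sidecar `<path>.json` records
#' `n_afferents`, `duration_ms` and `dt_ms`. [read_spike_pattern()]
#' round-trips exactly.
#'
#' @param pattern a [spike_pattern()].
#' @param path CSV file path; the sidecar replaces its extension by
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_spike_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "spike_pattern"))
  df <- data.frame(
    channel = rep(seq_len(pattern$n_afferents) - 1L, lengths(pattern$trains)),
    time_ms = unlist(pattern$trains, use.names = FALSE)
  )
  if (nrow(df) == 0) df <- df[0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(n_afferents = pattern$n_afferents, duration_ms = pattern$duration,
         dt_ms = pattern$dt),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spike pattern written by [write_spike_pattern()]
#'
#' @param path CSV file path with a `.json` sidecar alongside.
#' @return a [spike_pattern()].
#' @export
read_spike_pattern <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"))
  n <- as.integer(meta$n_afferents)
  df <- utils::read.csv(path)
  trains <- rep(list(numeric(0)), n)
  if (nrow(df)) {
    by_ch <- split(df$time_ms, factor(df$channel, levels = seq_len(n) - 1L))
    trains <- lapply(by_ch, function(t) sort(as.numeric(t)))
  }
  spike_pattern(trains, duration = as.numeric(meta$duration_ms),
                dt = as.numeric(meta$dt_ms))
}
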