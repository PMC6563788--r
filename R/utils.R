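`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the
#' previous RNG state afterwards, so generators behave as pure functions
#' of their arguments and seed. A `NULL` seed leaves the ambient RNG
#' stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: a function of (seed, k) only, so the
# k-th derived stream does not depend on how many streams are drawn.
subseed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 10007) %% 2147483646) + 1L
}

# 1-based column index of grid time t (t = 0 maps to column 1).
time_col <- function(t, dt) as.integer(round(t / dt)) + 1L

# Check spike times sit on the dt grid inside [0, duration], strictly
# increasing. Returns the times invisibly; stops otherwise.
check_times <- function(times, duration, dt, what = "spike train") {
  if (!length(times)) return(invisible(times))
  if (any(!is.finite(times))) stop(what, ": non-finite spike times")
  if (any(times < 0 | times > duration)) {
    stop(what, ": spike times outside [0, ", duration, "]")
  }
  if (any(abs(times / dt - round(times / dt)) > 1e-9)) {
    stop(what, ": spike times not on the ", dt, " ms grid")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop(what, ": spike times must be strictly increasing")
  }
  invisible(times)
}
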