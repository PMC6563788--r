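#' Gaussian-filtered spike train
#'
#' Convolves a spike train with a symmetric Gaussian
#' \eqn{f(t, \sigma) = \exp(-t^2 / 2\sigma^2)}, sampled at every grid
#' time in `[0, duration]`. Evaluation is exact over the whole grid (no
#' truncation window); with spike times on the grid the filter values
#' come from a tabulated lag profile, so results are bit-reproducible.
#'
#' @param train numeric spike times (ms).
#' @param sigma filter width (ms).
#' @param duration signal duration (ms).
#' @param dt grid step (ms).
#' @return numeric vector of length `duration/dt + 1`.
#' @export
gaussian_filter_train <- function(train, sigma = 2, duration, dt = 1) {
  stopifnot(sigma > 0)
  Tn <- time_col(duration, dt)
  if (!length(train)) return(numeric(Tn))
  check_times(sort(as.numeric(train)), duration, dt)
  g <- exp(-((0:(Tn - 1)) * dt)^2 / (2 * sigma^2))
  .profile_sum(time_col(sort(as.numeric(train)), dt), g, Tn)
}

#' Correlation-based spike train similarity
#'
#' Cosine similarity of the Gaussian-filtered actual and desired trains:
#' the dot product of the two filtered signals divided by the product of
#' their Euclidean norms. Identical nonempty trains give 1. The filtered
#' signals are nonnegative, so the value lies in `[0, 1]`. Conventions at
#' zero norm: both trains empty gives 1, exactly one empty gives 0.
#'
#' @param actual,desired numeric spike times (ms).
#' @param sigma Gaussian filter width (ms); 2 ms by default.
#' @param duration signal duration (ms).
#' @param dt grid step (ms).
#' @return similarity in `[0, 1]`.
#' @export
correlation_c <- function(actual, desired, sigma = 2, duration, dt = 1) {
  na <- length(actual); nd <- length(desired)
  if (na == 0 && nd == 0) return(1)
  if (na == 0 || nd == 0) return(0)
  vo <- gaussian_filter_train(actual, sigma, duration, dt)
  vd <- gaussian_filter_train(desired, sigma, duration, dt)
  val <- sum(vo * vd) / sqrt(sum(vo * vo) * sum(vd * vd))
  min(max(val, 0), 1)
}
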