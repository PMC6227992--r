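#' First derivative of a sampled series
#'
#' Central differences at interior samples, one-sided differences at the two
#' edges; second-order accurate in the interior, no phase shift.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of the same length, in units of `x` per second.
#' @export
deriv1 <- function(x, fs) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  if (n == 2L) {
    d[] <- (x[2] - x[1]) * fs
    return(d)
  }
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}

#' Convert a sample count to milliseconds
#'
#' `ms = samples / fs * 1000`, rounded half away from zero to `digits`
#' decimals (the convention used when reporting interpolated-run lengths:
#' integer ms for single runs, 0.1 ms for means).
#'
#' @param samples Numeric sample count(s).
#' @param fs Sampling rate in Hz.
#' @param digits Decimal places to round to (default 0).
#' @return Numeric milliseconds.
#' @export
samples_to_ms <- function(samples, fs = 240, digits = 0) {
  ms <- samples / fs * 1000
  p <- 10^digits
  sign(ms) * floor(abs(ms) * p + 0.5) / p
}

# Deterministic sub-seed derivation: a small multiplicative hash keeping the
# result a valid 32-bit R seed. Streams indexed by (i, j) are independent of
# execution order.
derive_seed <- function(master, i = 0L, j = 0L) {
  m <- 2147483629
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + i * 16807 + j * 69621 + 11) %% m
  as.integer(s)
}

# Linear-interpolation resampling of y (sampled on an implicit uniform grid)
# to n_out points spanning the same interval.
resample_linear <- function(y, n_out) {
  n <- length(y)
  if (n < 2L) stop("need at least 2 samples to resample", call. = FALSE)
  if (n == n_out) return(y)
  stats::approx(x = seq(0, 1, length.out = n), y = y,
                xout = seq(0, 1, length.out = n_out))$y
}

# cumulative trapezoid integral of y sampled at rate fs, starting at 0
cumtrapz_fs <- function(y, fs) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2)) / fs
}
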