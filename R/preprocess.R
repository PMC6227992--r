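#' Preprocessing parameter objects
#'
#' `spike_params()` controls electromagnetic spike detection and repair:
#' single-sample spikes are flagged where the double-differentiated position
#' series deviates from its trial mean by more than `z_threshold` standard
#' deviations, and repaired by interpolating across `repair_halfwidth`
#' adjacent samples either side. `smooth_params()` controls the local
#' weighted linear-regression (LOWESS-style) outlier pass: a first-degree
#' polynomial over a 5-sample moving window with tricube weights;
#' residuals beyond `residual_z_threshold` s.d. are flagged.
#' `filter_spec()` describes the zero-phase (bidirectional) low-pass
#' Butterworth filter: fourth order, 12 Hz cut-off by default.
#'
#' @param z_threshold Spike z threshold (s.d. units).
#' @param repair_halfwidth Samples replaced either side of a spike.
#' @return Parameter lists of class `imk_spike_params`, `imk_smooth_params`,
#'   `imk_filter_spec`.
#' @export
spike_params <- function(z_threshold = 3, repair_halfwidth = 3L) {
  stopifnot(z_threshold > 0, repair_halfwidth >= 1)
  structure(list(z_threshold = z_threshold,
                 repair_halfwidth = as.integer(repair_halfwidth)),
            class = "imk_spike_params")
}

#' @rdname spike_params
#' @param window Moving-window width in samples (odd, >= 3).
#' @param degree Local polynomial degree (1 = weighted linear).
#' @param residual_z_threshold Residual z threshold for flagging outliers.
#' @export
smooth_params <- function(window = 5L, degree = 1L, residual_z_threshold = 3) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be odd and >= 3", call. = FALSE)
  structure(list(window = window, degree = as.integer(degree),
                 residual_z_threshold = residual_z_threshold),
            class = "imk_smooth_params")
}

#' @rdname spike_params
#' @param order Filter order of each pass.
#' @param cutoff_hz Low-pass cut-off frequency in Hz.
#' @export
filter_spec <- function(order = 4L, cutoff_hz = 12) {
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 mode = "bidirectional"),
            class = "imk_filter_spec")
}

#' Detect single-sample electromagnetic spikes
#'
#' Flags samples whose per-axis second difference (the double-differentiated
#' position series) deviates from that trial-and-axis mean by more than
#' `z_threshold` standard deviations; the flag sets of the three position
#' axes are unioned. The second difference at index `i` spans samples
#' `i-1, i, i+1`; the centre sample is reported.
#'
#' @param traj An `imk_trajectory`.
#' @param params An `imk_spike_params`.
#' @return Sorted integer vector of flagged sample indices.
#' @export
detect_spikes <- function(traj, params = spike_params()) {
  assert_trajectory(traj, 5L, "detect_spikes")
  flagged <- integer(0)
  for (ax in 1:3) {
    d2 <- diff(traj$xyz[, ax], differences = 2)
    s <- stats::sd(d2)
    if (!is.finite(s) || s == 0) next
    z <- abs(d2 - mean(d2)) / s
    flagged <- union(flagged, which(z > params$z_threshold) + 1L)
  }
  sort(flagged)
}

# merge index windows [i-hw, i+hw] into disjoint runs; returns a list of
# c(start, end) pairs clamped to [1, n]
merge_windows <- function(indices, halfwidth, n) {
  if (!length(indices)) return(list())
  indices <- as.integer(indices)
  lo <- pmax(1L, indices - as.integer(halfwidth))
  hi <- pmin(as.integer(n), indices + as.integer(halfwidth))
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out <- list(); cs <- lo[1]; ce <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= ce + 1L) ce <- max(ce, hi[i])
    else { out[[length(out) + 1L]] <- c(cs, ce); cs <- lo[i]; ce <- hi[i] }
  }
  out[[length(out) + 1L]] <- c(cs, ce)
  out
}

# replace samples in each merged window by linear interpolation between the
# flanking anchor samples (window start - 1 and window end + 1), clamping to
# the nearest valid anchor at the series boundaries
linear_repair <- function(x, windows) {
  n <- length(x)
  for (w in windows) {
    a <- w[1] - 1L; b <- w[2] + 1L
    if (a < 1L && b > n) next
    if (a < 1L) { x[w[1]:w[2]] <- x[b]; next }
    if (b > n) { x[w[1]:w[2]] <- x[a]; next }
    idx <- w[1]:w[2]
    x[idx] <- x[a] + (x[b] - x[a]) * (idx - a) / (b - a)
  }
  x
}

#' Repair flagged spikes by local interpolation
#'
#' For each flagged index `i`, samples `i - hw ... i + hw`
#' (`hw = repair_halfwidth`, default 3) are replaced, on every position axis,
#' by linear interpolation between the anchor samples `i - hw - 1` and
#' `i + hw + 1`. Overlapping or adjacent repair windows are merged, not
#' stacked; windows at the series boundary are clamped to the nearest valid
#' anchor.
#'
#' @param traj An `imk_trajectory`.
#' @param indices Flagged sample indices (from [detect_spikes()]).
#' @param params An `imk_spike_params`.
#' @return The repaired `imk_trajectory`.
#' @export
repair_spikes <- function(traj, indices, params = spike_params()) {
  assert_trajectory(traj, 5L, "repair_spikes")
  if (!length(indices)) return(traj)
  wins <- merge_windows(as.integer(indices), params$repair_halfwidth,
                        nrow(traj$xyz))
  for (ax in 1:3) traj$xyz[, ax] <- linear_repair(traj$xyz[, ax], wins)
  traj
}

# tricube-weighted degree-1 local fit over a centred moving window,
# evaluated at the window centre (MATLAB 'lowess'-style smoothing)
local_linear_smooth <- function(x, window) {
  n <- length(x)
  hw <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    idx <- lo:hi
    d <- abs(idx - i)
    dmax <- max(d, 1L)
    w <- (1 - (d / (dmax + 1e-9))^3)^3
    xc <- idx - i
    sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
    swy <- sum(w * x[idx]); swxy <- sum(w * xc * x[idx])
    det <- sw * swx2 - swx^2
    out[i] <- if (abs(det) < 1e-12) swy / sw
              else (swx2 * swy - swx * swxy) / det
  }
  out
}

#' Flag residual outliers with a local weighted linear smoother
#'
#' Smooths each position axis with a weighted linear least-squares fit
#' (first-degree polynomial, tricube weights) over a moving window of
#' `window` samples, and flags samples whose residual from the local fit
#' exceeds `residual_z_threshold` standard deviations of that axis's
#' residuals. Flag sets are unioned over axes. Intended as a second pass
#' after [detect_spikes()] for artifacts the double-differentiation rule
#' misses.
#'
#' @param traj An `imk_trajectory`.
#' @param params An `imk_smooth_params`.
#' @return Sorted integer vector of flagged sample indices.
#' @seealso [repair_spikes()] for the repair applied to these indices.
#' @export
lowess_outliers <- function(traj, params = smooth_params()) {
  assert_trajectory(traj, params$window, "lowess_outliers")
  flagged <- integer(0)
  for (ax in 1:3) {
    res <- traj$xyz[, ax] - local_linear_smooth(traj$xyz[, ax], params$window)
    s <- stats::sd(res)
    # numerically noiseless axes (residuals at rounding level) carry no
    # outlier information
    if (!is.finite(s) || s <= 1e-8 * max(1, stats::sd(traj$xyz[, ax]))) next
    flagged <- union(flagged, which(abs(res) > params$residual_z_threshold * s))
  }
  sort(flagged)
}

#' Excise stimulation-locked artifact windows and spline-interpolate
#'
#' Removes every sample within `window_ms / 2` ms either side of each
#' artifact onset (the stimulation pulse times), merges overlapping windows,
#' and replaces the removed samples on each axis with a cubic spline fitted
#' to the remaining data. Cubic polynomials are reconstructed exactly. An
#' interpolation report lists the per-period lengths, their total, and the
#' maximum run, in samples and milliseconds.
#'
#' @param traj An `imk_trajectory`.
#' @param onsets_s Artifact onset times (s).
#' @param window_ms Full excision window width per onset (ms); default 50
#'   (25 ms either side).
#' @return The interpolated `imk_trajectory`, with attribute `"report"`: a
#'   list with `n_periods`, `period_lengths`, `total_samples`, `max_run`,
#'   `total_ms`, `max_run_ms`, `period_lengths_ms`.
#' @export
excise_tms_artifacts <- function(traj, onsets_s, window_ms = 50) {
  assert_trajectory(traj, 8L, "excise_tms_artifacts")
  if (window_ms <= 0) stop("window_ms must be positive", call. = FALSE)
  n <- nrow(traj$xyz)
  fs <- traj$fs
  if (!length(onsets_s)) {
    attr(traj, "report") <- list(n_periods = 0L, period_lengths = integer(0),
                                 total_samples = 0L, max_run = 0L,
                                 total_ms = 0, max_run_ms = 0,
                                 period_lengths_ms = numeric(0))
    return(traj)
  }
  t_max <- (n - 1) / fs
  if (any(onsets_s < 0 | onsets_s > t_max))
    stop("artifact onsets outside the trial", call. = FALSE)
  centre <- round(onsets_s * fs) + 1L
  hw <- max(1L, round(window_ms / 2 / 1000 * fs))
  wins <- merge_windows(centre, hw, n)
  removed <- unlist(lapply(wins, function(w) w[1]:w[2]))
  frac <- length(removed) / n
  if (frac > 0.9)
    stop("artifact windows cover more than 90% of the trial", call. = FALSE)
  if (frac > 0.5)
    warning("artifact windows cover more than 50% of the trial")
  keep <- setdiff(seq_len(n), removed)
  for (ax in 1:3) {
    sf <- stats::splinefun(keep, traj$xyz[keep, ax], method = "fmm")
    traj$xyz[removed, ax] <- sf(removed)
  }
  lens <- vapply(wins, function(w) w[2] - w[1] + 1L, integer(1))
  attr(traj, "report") <- list(
    n_periods = length(lens), period_lengths = lens,
    total_samples = sum(lens), max_run = max(lens),
    total_ms = samples_to_ms(sum(lens), fs, 1),
    max_run_ms = samples_to_ms(max(lens), fs, 0),
    period_lengths_ms = samples_to_ms(lens, fs, 0))
  traj
}

# ---- zero-phase Butterworth filtering -------------------------------------
#
# signal::butter supplies the coefficients; the forward/reverse application
# is done here with direct-form-II-transposed recursion, steady-state initial
# conditions and odd-reflection padding (the classical filtfilt scheme), so a
# constant input passes through exactly and edges carry no startup transient.

iir_apply <- function(b, a, x, zi = NULL) {
  nb <- length(b); na <- length(a)
  m <- max(nb, na)
  b <- c(b, numeric(m - nb)); a <- c(a, numeric(m - na))
  b <- b / a[1]; a <- a / a[1]
  n <- length(x)
  y <- numeric(n)
  z <- if (is.null(zi)) numeric(m - 1) else zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 2) {
      for (k in 1:(m - 2)) z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    }
    z[m - 1] <- b[m] * xi - a[m] * yi
    y[i] <- yi
  }
  y
}

# steady-state filter state for a unit-amplitude step (lfilter_zi)
iir_zi <- function(b, a) {
  m <- max(length(b), length(a))
  b <- c(b, numeric(m - length(b))); a <- c(a, numeric(m - length(a)))
  b <- b / a[1]; a <- a / a[1]
  A <- rbind(-a[-1], cbind(diag(m - 2), numeric(m - 2)))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m - 1) - t(A), B)
}

filtfilt_zero <- function(b, a, x) {
  m <- max(length(b), length(a))
  nfact <- 3L * (m - 1L)
  n <- length(x)
  if (n <= nfact)
    stop("series too short for the requested filter (need > ", nfact,
         " samples)", call. = FALSE)
  pre <- 2 * x[1] - x[(nfact + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - nfact)]
  xp <- c(pre, x, post)
  zi <- iir_zi(b, a)
  y <- iir_apply(b, a, xp, zi * xp[1])
  y <- rev(iir_apply(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

#' Zero-phase low-pass filtering of a trajectory
#'
#' Applies the Butterworth design of `spec` forward and backward over each
#' position axis (bidirectional, zero-phase; the magnitude response of the
#' two passes combined is the squared single-pass response). DC gain is
#' exactly 1.
#'
#' @param traj An `imk_trajectory`.
#' @param spec An `imk_filter_spec`.
#' @return The filtered `imk_trajectory`.
#' @export
lowpass <- function(traj, spec = filter_spec()) {
  assert_trajectory(traj, 2L, "lowpass")
  if (spec$cutoff_hz >= traj$fs / 2)
    stop("cut-off must lie below the Nyquist frequency", call. = FALSE)
  bt <- signal::butter(spec$order, spec$cutoff_hz / (traj$fs / 2))
  for (ax in 1:3) traj$xyz[, ax] <- filtfilt_zero(bt$b, bt$a, traj$xyz[, ax])
  traj
}

#' Full preprocessing chain for one trajectory
#'
#' Spike detection and repair, local-regression outlier repair, optional
#' stimulation-artifact excision with spline interpolation, then zero-phase
#' low-pass filtering — the order in which the cleaning stages are meant to
#' run.
#'
#' @param traj An `imk_trajectory`.
#' @param artifact_onsets_s Stimulation artifact onset times (s), or empty.
#' @param spike An `imk_spike_params`.
#' @param smooth An `imk_smooth_params`.
#' @param filt An `imk_filter_spec`.
#' @param tms_window_ms Excision window width (ms).
#' @return The cleaned `imk_trajectory` with attribute `"report"` from the
#'   excision stage.
#' @export
preprocess_trajectory <- function(traj, artifact_onsets_s = numeric(0),
                                  spike = spike_params(),
                                  smooth = smooth_params(),
                                  filt = filter_spec(),
                                  tms_window_ms = 50) {
  traj <- repair_spikes(traj, detect_spikes(traj, spike), spike)
  traj <- repair_spikes(traj, lowess_outliers(traj, smooth), spike)
  traj <- excise_tms_artifacts(traj, artifact_onsets_s, tms_window_ms)
  rep <- attr(traj, "report")
  traj <- lowpass(traj, filt)
  attr(traj, "report") <- rep
  traj
}

#' Preprocess every trajectory of a trial
#'
#' Runs [preprocess_trajectory()] over all 16 channels, using the trial's
#' recorded artifact onsets.
#'
#' @inheritParams preprocess_trajectory
#' @param trial An `imk_trial`.
#' @return The cleaned `imk_trial`; attribute `"reports"` holds the
#'   per-channel interpolation reports.
#' @export
preprocess_trial <- function(trial, spike = spike_params(),
                             smooth = smooth_params(), filt = filter_spec(),
                             tms_window_ms = 50) {
  reports <- list()
  for (ch in names(trial$trajectories)) {
    tr <- preprocess_trajectory(trial$trajectories[[ch]],
                                trial$artifact_onsets_s, spike, smooth,
                                filt, tms_window_ms)
    reports[[ch]] <- attr(tr, "report")
    attr(tr, "report") <- NULL
    trial$trajectories[[ch]] <- tr
  }
  attr(trial, "reports") <- reports
  trial
}
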