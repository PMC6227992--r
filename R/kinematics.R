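#' Segmentation and exclusion parameters
#'
#' The primary movement runs from movement onset to gesture completion,
#' delimited by a 12 cm/s speed threshold. Trials are excluded when the
#' participant started moving before the go tone, failed to finish within
#' 200 ms of the return tone, or any tracker exceeded 250 cm/s.
#'
#' @param movement_threshold_cm_s Speed threshold delimiting the movement.
#' @param max_speed_cm_s Overspeed exclusion threshold.
#' @param finish_tolerance_ms Grace period after the return tone.
#' @param max_movement_time_ms Maximum accepted movement time.
#' @return An object of class `imk_seg_params`.
#' @export
seg_params <- function(movement_threshold_cm_s = 12, max_speed_cm_s = 250,
                       finish_tolerance_ms = 200, max_movement_time_ms = 1800) {
  stopifnot(movement_threshold_cm_s > 0,
            movement_threshold_cm_s < max_speed_cm_s)
  structure(list(movement_threshold_cm_s = movement_threshold_cm_s,
                 max_speed_cm_s = max_speed_cm_s,
                 finish_tolerance_ms = finish_tolerance_ms,
                 max_movement_time_ms = max_movement_time_ms),
            class = "imk_seg_params")
}

#' Three-dimensional speed of a trajectory
#'
#' Per-sample Euclidean norm of the position derivative (central differences
#' at interior samples, one-sided at the edges).
#'
#' @param traj An `imk_trajectory`.
#' @return Numeric vector of speeds in cm/s, one per sample.
#' @export
speed3d <- function(traj) {
  assert_trajectory(traj, 3L, "speed3d")
  dx <- deriv1(traj$xyz[, 1], traj$fs)
  dy <- deriv1(traj$xyz[, 2], traj$fs)
  dz <- deriv1(traj$xyz[, 3], traj$fs)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Segment the primary movement from a speed series
#'
#' Onset is the first sample at or above the movement threshold; completion
#' is the first sample after the global speed peak that falls strictly below
#' it. When the speed never reaches the threshold a "no movement" result is
#' returned; when it never falls back below before the series ends, the
#' segment is marked incomplete (used by the late-finish exclusion rule).
#'
#' @param speed Numeric speed series (cm/s), typically restricted to the
#'   response window.
#' @param params An `imk_seg_params`.
#' @return A list with `onset`, `peak`, `offset` (indices into `speed`),
#'   `moved` (logical) and `complete` (logical). `onset`/`offset` are `NA`
#'   when no movement was detected.
#' @export
segment_primary <- function(speed, params = seg_params()) {
  thr <- params$movement_threshold_cm_s
  above <- which(speed >= thr)
  if (!length(above))
    return(list(onset = NA_integer_, peak = NA_integer_,
                offset = NA_integer_, moved = FALSE, complete = FALSE))
  onset <- above[1]
  peak <- which.max(speed)
  n <- length(speed)
  offset <- NA_integer_; complete <- FALSE
  if (peak < n) {
    below <- which(speed[(peak + 1L):n] < thr)
    if (length(below)) { offset <- peak + below[1]; complete <- TRUE }
  }
  if (!complete) offset <- n
  list(onset = onset, peak = peak, offset = offset, moved = TRUE,
       complete = complete)
}

#' Resample a speed segment to 120 samples and normalize amplitude
#'
#' Linear-interpolation resampling of the segment to exactly 120 points,
#' followed by division by the segment maximum (resample, then normalize).
#'
#' @param speed_segment Numeric speed values over the primary movement
#'   (length >= 2).
#' @param n_out Number of output samples (120).
#' @return An object of class `imk_curve`: numeric vector of length
#'   `n_out`, maximum exactly 1.
#' @export
resample_normalize <- function(speed_segment, n_out = 120L) {
  if (length(speed_segment) < 2L)
    stop("segment must contain at least 2 samples", call. = FALSE)
  y <- resample_linear(speed_segment, n_out)
  m <- max(y)
  if (!is.finite(m) || m <= 0)
    stop("degenerate curve: segment maximum is not positive", call. = FALSE)
  structure(y / m, class = "imk_curve")
}

#' Peak kinematic parameters of a speed segment
#'
#' Peak velocity (PV) is the maximum speed; acceleration is the derivative
#' of the speed series (central differences); peak acceleration (PA) is its
#' maximum and peak deceleration (PD) its minimum (reported negative). Taken
#' on original, non-resampled segments.
#'
#' @param speed_segment Numeric speed values over the primary movement
#'   (length >= 3).
#' @param fs Sampling rate in Hz.
#' @return A list with `PV` (cm/s), `PA` (cm/s^2), `PD` (cm/s^2, <= 0).
#' @export
peak_params <- function(speed_segment, fs) {
  if (length(speed_segment) < 3L)
    stop("segment must contain at least 3 samples", call. = FALSE)
  acc <- deriv1(speed_segment, fs)
  list(PV = max(speed_segment), PA = max(acc), PD = min(acc))
}

#' Apply the trial exclusion rules
#'
#' Rules fire in fixed order and the first sets the reason:
#' `premature_start` (any imitator tracker at or above the movement
#' threshold in the 500 ms before the imitator's go tone), `late_finish`
#' (the imitator's primary movement is not completed within
#' `finish_tolerance_ms` of the return tone, judged on the fastest digit /
#' wrist tracker), `overspeed` (any of the 16 trackers exceeds
#' `max_speed_cm_s` anywhere in the trial).
#'
#' @param trial A preprocessed `imk_trial`.
#' @param params An `imk_seg_params`.
#' @return The trial with `excluded` / `exclusion_reason` set.
#' @export
apply_exclusions <- function(trial, params = seg_params()) {
  fs <- trial$trajectories[[1]]$fs
  n <- n_samples(trial$trajectories[[1]])
  tl <- trial$timeline
  go_i <- round(tl$imitator_go_tone_s * fs) + 1L
  end_i <- min(n, round((tl$imitator_hold_end_s +
                           params$finish_tolerance_ms / 1000) * fs) + 1L)
  pre_i <- max(1L, go_i - round(0.5 * fs))

  imit_chan <- paste("imitator", TRACKERS, sep = ".")
  speeds <- lapply(trial$trajectories, speed3d)

  reason <- NA_character_
  # premature start
  for (ch in imit_chan) {
    if (go_i > pre_i + 1L &&
        any(speeds[[ch]][pre_i:(go_i - 1L)] >= params$movement_threshold_cm_s)) {
      reason <- "premature_start"; break
    }
  }
  # late finish: gesture completion within the response window
  if (is.na(reason)) {
    env <- do.call(pmax, speeds[paste("imitator", c("wrist", DIGITS),
                                      sep = ".")])
    seg <- segment_primary(env[go_i:end_i], params)
    if (seg$moved && !seg$complete) reason <- "late_finish"
  }
  # overspeed anywhere, any tracker
  if (is.na(reason)) {
    for (ch in names(speeds)) {
      if (any(speeds[[ch]] > params$max_speed_cm_s)) {
        reason <- "overspeed"; break
      }
    }
  }
  trial$excluded <- !is.na(reason)
  trial$exclusion_reason <- reason
  trial
}

#' Per-trial kinematic extraction for one person
#'
#' Segments the primary movement of each tracker within the person's
#' response window and returns peak parameters plus the 120-sample
#' normalized curve.
#'
#' @param trial A preprocessed `imk_trial`.
#' @param person `"actor"` or `"imitator"`.
#' @param params An `imk_seg_params`.
#' @return A list keyed by tracker: each element has `segment`
#'   (onset/peak/offset indices relative to the response window), `peaks`
#'   ([peak_params()] output), `curve` (an `imk_curve`), or `NULL` for
#'   trackers with no movement.
#' @export
trial_kinematics <- function(trial, person = "imitator",
                             params = seg_params()) {
  person <- match.arg(person, PERSONS)
  fs <- trial$trajectories[[1]]$fs
  n <- n_samples(trial$trajectories[[1]])
  tl <- trial$timeline
  if (person == "imitator") {
    go_i <- round(tl$imitator_go_tone_s * fs) + 1L
    end_i <- min(n, round((tl$imitator_hold_end_s +
                             params$finish_tolerance_ms / 1000) * fs) + 1L)
  } else {
    go_i <- round(tl$actor_go_tone_s * fs) + 1L
    end_i <- min(n, round((tl$actor_hold_end_s +
                             params$finish_tolerance_ms / 1000) * fs) + 1L)
  }
  out <- list()
  for (tracker in TRACKERS) {
    sp <- speed3d(get_trajectory(trial, person, tracker))[go_i:end_i]
    seg <- segment_primary(sp, params)
    if (!seg$moved || is.na(seg$onset) || seg$offset - seg$onset < 2L) {
      out[[tracker]] <- NULL
      next
    }
    segment <- sp[seg$onset:seg$offset]
    out[[tracker]] <- list(segment = seg, peaks = peak_params(segment, fs),
                           curve = resample_normalize(segment))
  }
  out
}

#' Participant x condition means of digit peak parameters
#'
#' Averages the requested peak parameter over the five digit trackers
#' (thumb through little finger) per trial, then over retained trials per
#' participant and condition cell.
#'
#' @param records Data frame with columns `participant_id`, `site`,
#'   `stim_time`, `tracker`, the value column, and `excluded`.
#' @param which `"PV"` or `"PD"` — the value column to average.
#' @return Data frame of per-participant, per-cell means with column
#'   `mean_value`.
#' @export
mean_digit_params <- function(records, which = c("PV", "PD")) {
  which <- match.arg(which)
  if (!which %in% names(records))
    stop("records lack a `", which, "` column", call. = FALSE)
  keep <- records[!records$excluded & records$tracker %in% DIGITS, ,
                  drop = FALSE]
  if (!nrow(keep)) stop("no retained digit records", call. = FALSE)
  # per-trial digit mean, then per participant x cell
  trial_key <- interaction(keep$participant_id, keep$site, keep$stim_time,
                           keep$trial_index, drop = TRUE)
  per_trial <- stats::aggregate(keep[[which]],
                                by = list(key = trial_key,
                                          participant_id = keep$participant_id,
                                          site = keep$site,
                                          stim_time = keep$stim_time),
                                FUN = mean)
  out <- stats::aggregate(per_trial$x,
                          by = list(participant_id = per_trial$participant_id,
                                    site = per_trial$site,
                                    stim_time = per_trial$stim_time),
                          FUN = mean)
  names(out)[names(out) == "x"] <- "mean_value"
  out
}
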