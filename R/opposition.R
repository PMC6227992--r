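#' Epoch structure of the opposition task
#'
#' Three contiguous half-open epochs: pre-stimulation `[0, 5)` s,
#' stimulation `[5, 10)` s, post-stimulation `[10, 15]` s, with 15 pulses at
#' 3 Hz from 5.00 s.
#'
#' @param pre_end_s End of the pre-stimulation epoch (s).
#' @param stim_end_s End of the stimulation epoch (s).
#' @param post_end_s End of the recording (s).
#' @return An object of class `imk_epoch_spec`.
#' @export
epoch_spec <- function(pre_end_s = 5, stim_end_s = 10, post_end_s = 15) {
  stopifnot(0 < pre_end_s, pre_end_s < stim_end_s, stim_end_s < post_end_s)
  structure(list(pre = c(0, pre_end_s), stim = c(pre_end_s, stim_end_s),
                 post = c(stim_end_s, post_end_s),
                 stim_pulse_times_s = pulse_times(pre_end_s, 3, 14 / 3)),
            class = "imk_epoch_spec")
}

epoch_of <- function(t, epochs) {
  ifelse(t < epochs$pre[2], "pre",
         ifelse(t < epochs$stim[2], "stim",
                ifelse(t <= epochs$post[2], "post", NA_character_)))
}

#' Detect thumb-to-fingertip touches
#'
#' A touch is a local minimum of the thumb-fingertip distance falling below
#' the contact threshold; consecutive touches are separated by at least the
#' refractory gap. Each event is labelled with the finger whose distance was
#' minimal at that time.
#'
#' @param thumb An `imk_trajectory` for the thumb tip.
#' @param fingers Named list of four `imk_trajectory` objects (index,
#'   middle, ring, little).
#' @param contact_mm Contact distance threshold (mm).
#' @param min_gap_ms Refractory gap between successive touches (ms).
#' @return Data frame with columns `time_s`, `sample`, `digit`,
#'   `distance_mm`, sorted by time (empty, with a warning, when no finger
#'   ever comes within contact range).
#' @export
detect_touches <- function(thumb, fingers, contact_mm = 5, min_gap_ms = 100) {
  stopifnot(length(fingers) == 4L)
  fs <- thumb$fs
  n <- nrow(thumb$xyz)
  dist_mm <- sapply(fingers, function(f) {
    if (nrow(f$xyz) != n) stop("trajectories must be time-aligned", call. = FALSE)
    sqrt(rowSums((thumb$xyz - f$xyz)^2)) * 10
  })
  dmin <- apply(dist_mm, 1L, min)
  which_f <- names(fingers)[apply(dist_mm, 1L, which.min)]
  below <- dmin < contact_mm
  if (!any(below)) {
    warning("no thumb-fingertip contact within ", contact_mm, " mm")
    return(data.frame(time_s = numeric(0), sample = integer(0),
                      digit = character(0), distance_mm = numeric(0)))
  }
  # one candidate per contiguous sub-threshold excursion (its distance
  # minimum), then a refractory pass keeping the deeper of any two
  # candidates closer than min_gap_ms
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- mapply(function(s, e) s + which.min(dmin[s:e]) - 1L,
                 starts[r$values], ends[r$values])
  o <- order(dmin[cand])
  gap <- round(min_gap_ms / 1000 * fs)
  chosen <- integer(0)
  for (i in cand[o]) {
    if (!length(chosen) || all(abs(chosen - i) >= gap)) chosen <- c(chosen, i)
  }
  chosen <- sort(chosen)
  data.frame(time_s = (chosen - 1) / fs, sample = chosen,
             digit = which_f[chosen], distance_mm = dmin[chosen])
}

#' Inter-touch interval statistics per epoch
#'
#' Intervals between consecutive touches (pooled across digits, the single
#' back-and-forth stream) are assigned to the epoch containing the later
#' touch. The mean needs at least 2 touches contributing an interval to the
#' epoch; the s.d. (sample form, n - 1 denominator) at least 2 intervals.
#'
#' @param touches Data frame from [detect_touches()].
#' @param epochs An `imk_epoch_spec`.
#' @return Data frame with one row per epoch (`pre`, `stim`, `post`):
#'   `n_intervals`, `iti_ms`, `iti_sd_ms` (`NA` where insufficient).
#' @export
iti_stats <- function(touches, epochs = epoch_spec()) {
  lv <- c("pre", "stim", "post")
  if (nrow(touches) < 2L) {
    return(data.frame(epoch = lv, n_intervals = 0L, iti_ms = NA_real_,
                      iti_sd_ms = NA_real_))
  }
  t <- sort(touches$time_s)
  iv <- diff(t) * 1000
  ep <- epoch_of(t[-1], epochs)
  out <- lapply(lv, function(e) {
    x <- iv[!is.na(ep) & ep == e]
    data.frame(epoch = e, n_intervals = length(x),
               iti_ms = if (length(x) >= 1) mean(x) else NA_real_,
               iti_sd_ms = if (length(x) >= 2) stats::sd(x) else NA_real_)
  })
  do.call(rbind, out)
}

#' Mean finger and thumb speeds per epoch
#'
#' Time-average of the 3-D speed within each half-open epoch; the four
#' fingertip trackers are averaged into the finger speed.
#'
#' @param trajectories Named list with `thumb` plus the four finger
#'   trajectories.
#' @param epochs An `imk_epoch_spec`.
#' @return Data frame with one row per epoch: `finger_speed_cm_s`,
#'   `thumb_speed_cm_s`.
#' @export
epoch_speeds <- function(trajectories, epochs = epoch_spec()) {
  fs <- trajectories$thumb$fs
  t <- time_axis(trajectories$thumb)
  ep <- epoch_of(t, epochs)
  thumb_sp <- speed3d(trajectories$thumb)
  fingers <- trajectories[c("index", "middle", "ring", "little")]
  finger_sp <- rowMeans(sapply(fingers, speed3d))
  lv <- c("pre", "stim", "post")
  do.call(rbind, lapply(lv, function(e) {
    i <- !is.na(ep) & ep == e
    data.frame(epoch = e,
               finger_speed_cm_s = mean(finger_sp[i]),
               thumb_speed_cm_s = mean(thumb_sp[i]))
  }))
}

#' Analyze one opposition recording end to end
#'
#' Touch detection, inter-touch-interval statistics and epoch speeds, the
#' per-recording measure set of the opposition task.
#'
#' @param trajectories Named trajectory list (`thumb`, `index`, `middle`,
#'   `ring`, `little`).
#' @param epochs An `imk_epoch_spec`.
#' @param contact_mm,min_gap_ms Passed to [detect_touches()].
#' @return An object of class `imk_opposition_result`: list with `touches`,
#'   `iti`, `speeds`.
#' @export
opposition_result <- function(trajectories, epochs = epoch_spec(),
                              contact_mm = 5, min_gap_ms = 100) {
  fingers <- trajectories[c("index", "middle", "ring", "little")]
  touches <- detect_touches(trajectories$thumb, fingers, contact_mm,
                            min_gap_ms)
  structure(list(touches = touches,
                 iti = iti_stats(touches, epochs),
                 speeds = epoch_speeds(trajectories, epochs)),
            class = "imk_opposition_result")
}

#' @export
print.imk_opposition_result <- function(x, ...) {
  cat(sprintf("<imk_opposition_result> %d touches\n", nrow(x$touches)))
  print(merge(x$speeds, x$iti, by = "epoch", sort = FALSE))
  invisible(x)
}
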