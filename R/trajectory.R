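#' @keywords internal
"_PACKAGE"

#' Tracker and person label sets
#'
#' The eight tracker sites recorded per person (shoulder, elbow, wrist, and
#' the five digit tips) and the two persons of a two-person imitation trial.
#'
#' @format Character vectors.
#' @name label-sets
NULL

#' @rdname label-sets
#' @export
TRACKERS <- c("shoulder", "elbow", "wrist",
              "thumb", "index", "middle", "ring", "little")

#' @rdname label-sets
#' @export
DIGITS <- c("thumb", "index", "middle", "ring", "little")

#' @rdname label-sets
#' @export
PERSONS <- c("actor", "imitator")

#' Stimulation sites, times and stimulus classes
#' @rdname label-sets
#' @export
SITES <- c("PMv", "PMd", "vertex")

#' @rdname label-sets
#' @export
STIM_TIMES <- c("observation", "imitation")

#' @rdname label-sets
#' @export
MEANINGS <- c("meaningful", "meaningless")

#' @rdname label-sets
#' @export
EFFECTORS <- c("hand", "finger")

#' Construct a tracker trajectory
#'
#' A trajectory is one tracker's 6-d.f. recording: x/y/z position (cm) and
#' azimuth/elevation/roll orientation (degrees) sampled at a fixed rate.
#' Orientation channels are carried and round-tripped but not analysed.
#'
#' @param tracker_id One of [TRACKERS].
#' @param person One of [PERSONS].
#' @param fs Sampling rate in Hz (study value 240).
#' @param xyz Numeric matrix, n x 3, positions in cm.
#' @param angles Numeric matrix, n x 3, azimuth/elevation/roll in degrees.
#'   Defaults to zeros.
#' @return An object of class `imk_trajectory`: a list with fields
#'   `tracker_id`, `person`, `fs`, `xyz`, `angles`.
#' @export
trajectory <- function(tracker_id, person, fs, xyz, angles = NULL) {
  tracker_id <- match.arg(tracker_id, TRACKERS)
  person <- match.arg(person, PERSONS)
  xyz <- as.matrix(xyz)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (ncol(xyz) != 3L || nrow(xyz) < 1L)
    stop("`xyz` must be a non-empty n x 3 matrix", call. = FALSE)
  if (is.null(angles)) angles <- matrix(0, nrow(xyz), 3L)
  angles <- as.matrix(angles)
  if (!all(dim(angles) == dim(xyz)))
    stop("`angles` must match the dimensions of `xyz`", call. = FALSE)
  colnames(xyz) <- c("x_cm", "y_cm", "z_cm")
  colnames(angles) <- c("azimuth_deg", "elevation_deg", "roll_deg")
  structure(
    list(tracker_id = tracker_id, person = person, fs = fs,
         xyz = xyz, angles = angles),
    class = "imk_trajectory"
  )
}

#' @export
print.imk_trajectory <- function(x, ...) {
  cat(sprintf("<imk_trajectory> %s/%s: %d samples at %g Hz\n",
              x$person, x$tracker_id, nrow(x$xyz), x$fs))
  invisible(x)
}

#' Number of samples in a trajectory
#' @param traj An `imk_trajectory`.
#' @return Integer sample count.
#' @export
n_samples <- function(traj) nrow(traj$xyz)

#' Time stamps of a trajectory
#' @param traj An `imk_trajectory`.
#' @return Numeric vector of times in seconds, 0-based.
#' @export
time_axis <- function(traj) (seq_len(nrow(traj$xyz)) - 1) / traj$fs

assert_trajectory <- function(traj, min_samples = 1L, fun = "this operation") {
  if (!inherits(traj, "imk_trajectory"))
    stop(sprintf("%s requires an `imk_trajectory`", fun), call. = FALSE)
  if (nrow(traj$xyz) < min_samples)
    stop(sprintf("%s requires at least %d samples (got %d)",
                 fun, min_samples, nrow(traj$xyz)), call. = FALSE)
  invisible(traj)
}
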