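#' Write a trial to disk
#'
#' Emits two files: a tracker table CSV (`<path>.csv`) with columns
#' `t_s, person, tracker, x_cm, y_cm, z_cm, azimuth_deg, elevation_deg,
#' roll_deg`, one row per (time, person, tracker), and a metadata JSON
#' (`<path>.json`) carrying participant, session, condition labels, timeline,
#' artifact onsets and the exclusion flag. Numeric values are written with 17
#' significant digits, which round-trips IEEE doubles exactly.
#'
#' @param trial An `imk_trial`.
#' @param path Base path (without extension).
#' @return `path`, invisibly.
#' @seealso [read_trial()]
#' @export
write_trial <- function(trial, path) {
  if (!inherits(trial, "imk_trial")) stop("not an `imk_trial`", call. = FALSE)
  rows <- lapply(trial_channel_names(), function(ch) {
    tr <- trial$trajectories[[ch]]
    if (nrow(tr$xyz) < 1L) stop("empty trajectory in channel ", ch, call. = FALSE)
    data.frame(t_s = time_axis(tr), person = tr$person, tracker = tr$tracker_id,
               x_cm = tr$xyz[, 1], y_cm = tr$xyz[, 2], z_cm = tr$xyz[, 3],
               azimuth_deg = tr$angles[, 1], elevation_deg = tr$angles[, 2],
               roll_deg = tr$angles[, 3])
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)

  meta <- list(
    participant_id = trial$participant_id,
    session = trial$session,
    fs = trial$trajectories[[1]]$fs,
    condition = trial$condition,
    timeline = unclass(trial$timeline),
    artifact_onsets_s = as.numeric(trial$artifact_onsets_s),
    excluded = isTRUE(trial$excluded),
    exclusion_reason = trial$exclusion_reason
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a trial from disk
#'
#' Reads the CSV/JSON pair written by [write_trial()], validating the schema:
#' all 16 (person, tracker) channels must be present with a strictly
#' increasing, shared time column.
#'
#' @param path Base path (without extension).
#' @return An `imk_trial`.
#' @export
read_trial <- function(path) {
  csv <- paste0(path, ".csv"); jsn <- paste0(path, ".json")
  if (!file.exists(csv)) stop("tracker table not found: ", csv, call. = FALSE)
  if (!file.exists(jsn)) stop("trial metadata not found: ", jsn, call. = FALSE)
  tab <- utils::read.csv(csv, colClasses = c(
    t_s = "numeric", person = "character", tracker = "character",
    x_cm = "numeric", y_cm = "numeric", z_cm = "numeric",
    azimuth_deg = "numeric", elevation_deg = "numeric", roll_deg = "numeric"))
  need <- c("t_s", "person", "tracker", "x_cm", "y_cm", "z_cm",
            "azimuth_deg", "elevation_deg", "roll_deg")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("tracker table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  fs <- meta$fs

  chans <- split(tab, paste(tab$person, tab$tracker, sep = "."))
  missing <- setdiff(trial_channel_names(), names(chans))
  if (length(missing))
    stop("schema error: absent (person, tracker) channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  trajs <- lapply(chans[trial_channel_names()], function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    if (any(diff(d$t_s) <= 0))
      stop("format error: non-monotone time column in channel ",
           d$person[1], ".", d$tracker[1], call. = FALSE)
    trajectory(d$tracker[1], d$person[1], fs,
               cbind(d$x_cm, d$y_cm, d$z_cm),
               cbind(d$azimuth_deg, d$elevation_deg, d$roll_deg))
  })

  tl <- meta$timeline
  timeline <- trial_timeline(tl$image_onset_s, tl$stim_condition,
                             tl$stim_rate_hz, tl$stim_duration_s,
                             tl$inter_train_gap_s)
  trial(trajs, timeline, as.list(meta$condition),
        participant_id = meta$participant_id, session = meta$session,
        artifact_onsets_s = as.numeric(meta$artifact_onsets_s),
        excluded = isTRUE(meta$excluded),
        exclusion_reason = if (is.null(meta$exclusion_reason)) NA_character_
                           else meta$exclusion_reason)
}

#' Write / read an experiment manifest
#'
#' The manifest is a JSON file listing the trials of a generated or recorded
#' experiment with their condition labels and the relative base paths of the
#' trial files.
#'
#' @param manifest Data frame with columns `participant_id`, `session`,
#'   `site`, `stim_time`, `meaning`, `effector`, `path`.
#' @param path File path of the manifest JSON.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the data
#'   frame.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(trials = manifest), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)$trials
}
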