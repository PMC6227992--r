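#' Construct the event timeline of an imitation trial
#'
#' Times are seconds from trial start. The actor's go tone sounds 1000 ms
#' after image presentation; the actor performs and holds the gesture until a
#' return tone 2000 ms later. The imitator's go tone sounds 1000 ms after the
#' actor's return signal, with the same 2000 ms hold. rTMS trains run for 3 s
#' at 3 Hz: during observation they start 333 ms after image onset, during
#' imitation 1000 ms before the imitator's go tone.
#'
#' @param image_onset_s Image presentation time (s).
#' @param stim_condition `"observation"`, `"imitation"` or `"none"`.
#' @param stim_rate_hz Pulse rate of the stimulation train (Hz).
#' @param stim_duration_s Train duration (s).
#' @param inter_train_gap_s Minimum gap between trains (s).
#' @return An object of class `imk_timeline` (a named list of event times).
#' @export
trial_timeline <- function(image_onset_s = 0.3,
                           stim_condition = c("observation", "imitation", "none"),
                           stim_rate_hz = 3, stim_duration_s = 3,
                           inter_train_gap_s = 10) {
  stim_condition <- match.arg(stim_condition)
  actor_go <- image_onset_s + 1.0
  actor_hold_end <- actor_go + 2.0
  imitator_go <- actor_hold_end + 1.0
  imitator_hold_end <- imitator_go + 2.0
  stim_onset <- switch(stim_condition,
                       observation = image_onset_s + 0.333,
                       imitation = imitator_go - 1.0,
                       none = NA_real_)
  tl <- structure(
    list(image_onset_s = image_onset_s,
         actor_go_tone_s = actor_go,
         actor_hold_end_s = actor_hold_end,
         imitator_go_tone_s = imitator_go,
         imitator_hold_end_s = imitator_hold_end,
         stim_condition = stim_condition,
         stim_onset_s = stim_onset,
         stim_rate_hz = stim_rate_hz,
         stim_duration_s = stim_duration_s,
         inter_train_gap_s = inter_train_gap_s),
    class = "imk_timeline"
  )
  ev <- c(tl$image_onset_s, tl$actor_go_tone_s, tl$actor_hold_end_s,
          tl$imitator_go_tone_s, tl$imitator_hold_end_s)
  if (any(diff(ev) < 0)) stop("timeline events must be non-decreasing", call. = FALSE)
  tl
}

#' Pulse times of a stimulation train
#'
#' A train at `rate_hz` delivers its first pulse at `onset_s` and subsequent
#' pulses every `1/rate_hz` seconds while they still start within
#' `duration_s` of the onset. A 3 Hz train from 5.00 to 9.67 s delivers 15
#' pulses.
#'
#' @param onset_s Train onset (s).
#' @param rate_hz Pulse rate (Hz).
#' @param duration_s Train duration (s); pulses at `onset_s + k/rate_hz`
#'   for `k = 0, 1, ...` with `k/rate_hz <= duration_s` (endpoints
#'   inclusive, so a 3 Hz train spanning 4.67 s delivers 15 pulses).
#' @return Numeric vector of pulse times (s).
#' @export
pulse_times <- function(onset_s, rate_hz = 3, duration_s = 3) {
  if (is.na(onset_s)) return(numeric(0))
  k <- 0:ceiling(rate_hz * duration_s)
  t <- onset_s + k / rate_hz
  t[k / rate_hz <= duration_s + 1e-9]
}

#' Construct an imitation trial
#'
#' A trial bundles the 16 trajectories (8 trackers x 2 persons), its event
#' timeline, the condition labels, and artifact bookkeeping.
#'
#' @param trajectories List of 16 `imk_trajectory` objects, one per
#'   (person, tracker) pair, named `"person.tracker"`.
#' @param timeline An `imk_timeline`.
#' @param condition Named list with `site`, `stim_time`, `meaning`,
#'   `effector` drawn from [SITES], [STIM_TIMES], [MEANINGS], [EFFECTORS].
#' @param participant_id Participant identifier.
#' @param session Session number.
#' @param artifact_onsets_s Times of stimulation artifacts (s).
#' @param excluded Logical exclusion flag.
#' @param exclusion_reason Reason string when excluded.
#' @return An object of class `imk_trial`.
#' @export
trial <- function(trajectories, timeline, condition, participant_id = 1L,
                  session = 1L, artifact_onsets_s = numeric(0),
                  excluded = FALSE, exclusion_reason = NA_character_) {
  expected <- trial_channel_names()
  missing <- setdiff(expected, names(trajectories))
  if (length(missing))
    stop("trial requires 16 trajectories; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(trajectories), expected)
  if (length(extra))
    stop("unknown trajectory channels: ", paste(extra, collapse = ", "),
         call. = FALSE)
  ns <- vapply(trajectories, n_samples, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all 16 trajectories must have the same sample count", call. = FALSE)
  condition$site <- match.arg(condition$site, SITES)
  condition$stim_time <- match.arg(condition$stim_time, STIM_TIMES)
  condition$meaning <- match.arg(condition$meaning, MEANINGS)
  condition$effector <- match.arg(condition$effector, EFFECTORS)
  structure(
    list(trajectories = trajectories[expected], timeline = timeline,
         condition = condition, participant_id = participant_id,
         session = session, artifact_onsets_s = artifact_onsets_s,
         excluded = excluded, exclusion_reason = exclusion_reason),
    class = "imk_trial"
  )
}

trial_channel_names <- function() {
  as.vector(outer(PERSONS, TRACKERS, paste, sep = "."))
}

#' @export
print.imk_trial <- function(x, ...) {
  cat(sprintf(
    "<imk_trial> participant %s, session %s | %s/%s/%s/%s | %d samples%s\n",
    x$participant_id, x$session, x$condition$site, x$condition$stim_time,
    x$condition$meaning, x$condition$effector,
    n_samples(x$trajectories[[1]]),
    if (isTRUE(x$excluded)) paste0(" [excluded: ", x$exclusion_reason, "]") else ""))
  invisible(x)
}

#' Fetch one trajectory from a trial
#' @param trial An `imk_trial`.
#' @param person One of [PERSONS].
#' @param tracker One of [TRACKERS].
#' @return The requested `imk_trajectory`.
#' @export
get_trajectory <- function(trial, person, tracker) {
  trial$trajectories[[paste(person, tracker, sep = ".")]]
}

#' Experiment design description
#'
#' The study design: 12 participants, 3 sessions each (one stimulation site
#' per session), 64 trials per session, 8 trackers per person.
#'
#' @param n_participants Number of participants.
#' @param sessions_per_participant Sessions per participant (one site each).
#' @param trials_per_session Trials per session.
#' @return An object of class `imk_design`.
#' @export
experiment_design <- function(n_participants = 12L,
                              sessions_per_participant = 3L,
                              trials_per_session = 64L) {
  stopifnot(n_participants >= 1, sessions_per_participant >= 1,
            trials_per_session >= 1)
  if (sessions_per_participant > length(SITES))
    stop("at most one session per stimulation site", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         sessions_per_participant = as.integer(sessions_per_participant),
         trials_per_session = as.integer(trials_per_session),
         trackers_per_person = 8L),
    class = "imk_design"
  )
}
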