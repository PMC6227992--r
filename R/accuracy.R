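#' Correlation of actor and imitator velocity curves
#'
#' Pearson correlation of the paired samples of two 120-sample normalized
#' speed curves — the per-trial, per-tracker imitation-accuracy score.
#' Correlation is invariant to the amplitude normalization (which matters
#' for plotting, not for r).
#'
#' @param actor,imitator `imk_curve` objects or numeric vectors of equal
#'   length (120).
#' @return Pearson r, or `NA` with a warning when either curve has zero
#'   variance (undefined correlation; such records are dropped upstream).
#' @export
curve_correlation <- function(actor, imitator) {
  a <- as.numeric(actor); b <- as.numeric(imitator)
  if (length(a) != length(b))
    stop("curves must have equal length", call. = FALSE)
  if (length(a) != 120L)
    stop("curves must be the 120-sample resampled form", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance curve: correlation undefined, record dropped")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Fisher's z transformation
#'
#' `Z = 0.5 * ln((1 + r) / (1 - r))` (equivalently `atanh(r)`), applied to
#' correlation values before averaging and parametric analysis. Correlations
#' at exactly +/-1 are clipped to `1 - 1e-7` in magnitude (Z ~ 8.06) so the
#' transform stays finite; a message notes the clip.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher z value(s); `NA` maps to `NA`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| must not exceed 1", call. = FALSE)
  clip <- !is.na(r) & abs(r) >= 1
  if (any(clip)) {
    message(sum(clip), " correlation(s) at |r| = 1 clipped to 1 - 1e-7")
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Per-trial accuracy records for a set of trials
#'
#' For every retained trial and tracker with a segmentable movement in both
#' persons, correlates the actor and imitator normalized curves and applies
#' Fisher's z.
#'
#' @param trials List of preprocessed `imk_trial` objects.
#' @param params An `imk_seg_params`.
#' @return Data frame with columns `participant_id`, `session`, `site`,
#'   `stim_time`, `meaning`, `effector`, `trial_index`, `tracker`, `r`, `Z`.
#' @export
accuracy_records <- function(trials, params = seg_params()) {
  rows <- list(); k <- 0L
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (isTRUE(tr$excluded)) next
    ka <- trial_kinematics(tr, "actor", params)
    ki <- trial_kinematics(tr, "imitator", params)
    for (tracker in TRACKERS) {
      if (is.null(ka[[tracker]]) || is.null(ki[[tracker]])) next
      r <- suppressWarnings(curve_correlation(ka[[tracker]]$curve,
                                              ki[[tracker]]$curve))
      if (is.na(r)) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = tr$participant_id, session = tr$session,
        site = tr$condition$site, stim_time = tr$condition$stim_time,
        meaning = tr$condition$meaning, effector = tr$condition$effector,
        trial_index = i, tracker = tracker, r = r, Z = fisher_z(r))
    }
  }
  if (!k) stop("no valid accuracy records", call. = FALSE)
  do.call(rbind, rows)
}

#' Participant x condition mean Fisher-z per tracker
#'
#' Averages the per-trial z values within each (participant, site,
#' stim_time, meaning, effector, tracker) cell — the input to the four-way
#' repeated-measures ANOVA. Missing cells are reported via the
#' `"missing_cells"` attribute.
#'
#' @param records Output of [accuracy_records()].
#' @return Data frame of cell means with column `mean_Z`.
#' @export
condition_means <- function(records) {
  out <- stats::aggregate(
    records$Z,
    by = list(participant_id = records$participant_id, site = records$site,
              stim_time = records$stim_time, meaning = records$meaning,
              effector = records$effector, tracker = records$tracker),
    FUN = mean)
  names(out)[names(out) == "x"] <- "mean_Z"
  full <- expand.grid(participant_id = unique(records$participant_id),
                      site = unique(records$site),
                      stim_time = unique(records$stim_time),
                      meaning = unique(records$meaning),
                      effector = unique(records$effector),
                      tracker = unique(records$tracker),
                      stringsAsFactors = FALSE)
  got <- do.call(paste, out[names(full)])
  want <- do.call(paste, full)
  attr(out, "missing_cells") <- full[!(want %in% got), , drop = FALSE]
  out
}
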