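#' Minimum-jerk reference profiles
#'
#' The canonical smooth reach model: position follows
#' `x(tau) = x0 + D * (10 tau^3 - 15 tau^4 + 6 tau^5)` over normalized time
#' `tau` in `[0, 1]`, giving the bell-shaped speed
#' `v(tau) = (D/T) * 30 tau^2 (1 - tau)^2` with peak `1.875 * D / T` at
#' `tau = 0.5`. These closed forms are the oracles for the generator and the
#' segmentation / peak-parameter tests.
#'
#' @param tau Normalized time in `[0, 1]`.
#' @return `minjerk_position`: normalized displacement in `[0, 1]`;
#'   `minjerk_speed`: normalized speed (multiply by `D/T` for units).
#' @export
minjerk_position <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' @rdname minjerk_position
#' @export
minjerk_speed <- function(tau) 30 * tau^2 * (1 - tau)^2

# Beta-profile speed family: dbeta(tau, a, b) generalizes the minimum-jerk
# speed (a = b = 3 gives 30 tau^2 (1-tau)^2 exactly); `shape` is the pair
# c(a, b). At fixed amplitude and duration, a peak-velocity factor f > 1 is
# realized by skewing the profile (a = 3, b > 3): the peak rises to
# f * 1.875 and moves earlier, lengthening the deceleration phase — the
# kinematic signature of a faster movement over the same path.
bell_mode <- function(shape) (shape[1] - 1) / (shape[1] + shape[2] - 2)

bell_peak <- function(shape) {
  stats::dbeta(bell_mode(shape), shape[1], shape[2])
}

shape_for_peak_factor <- function(factor) {
  if (factor <= 0) stop("peak-velocity factor must be positive", call. = FALSE)
  if (abs(factor - 1) < 1e-12) return(c(3, 3))
  target <- factor * bell_peak(c(3, 3))
  b <- stats::uniroot(function(b) bell_peak(c(3, b)) - target,
                      interval = c(2.05, 400), tol = 1e-10)$root
  c(3, b)
}

#' Synthetic-data generator specification
#'
#' Collects every knob of the synthetic actor-imitator experiment. The seed
#' fully determines all output. Defaults emulate the study's recording
#' conditions: 240 Hz sampling, ~1.2 s gestures, digit peak speeds near
#' 90 cm/s, actor-imitator velocity-curve coupling of 0.7, occasional
#' single-sample electromagnetic spikes, and stimulation-locked artifact
#' windows at the 3 Hz pulse times.
#'
#' @param seed Master seed (integer).
#' @param fs Sampling rate in Hz.
#' @param movement_duration_s Gesture duration in seconds.
#' @param peak_speed_cm_s Named vector of baseline peak speeds per tracker
#'   role (cm/s).
#' @param actor_imitator_coupling Target Pearson correlation of resampled
#'   actor/imitator speed curves, in `[0, 1]`.
#' @param effect_map List of condition effects; each element is
#'   `list(site=, stim_time=, trackers=, factor=)` applying a multiplicative
#'   peak-velocity factor to the imitator's listed trackers in that cell.
#' @param spike_rate Expected single-sample spikes per trial (whole trial,
#'   all channels pooled).
#' @param spike_amplitude_cm Displacement of an injected spike (cm).
#' @param tms_window_ms Full width of the injected stimulation artifact
#'   around each pulse (ms).
#' @param tms_amplitude_cm Amplitude of the injected artifact deflection (cm).
#' @param noise_sd_cm Gaussian position noise s.d. (cm).
#' @param movement_threshold_cm_s Speed threshold used to delimit the
#'   primary movement (cm/s); shared with the analysis default.
#' @param curve_noise_k Number of sinusoidal basis components of the smooth
#'   velocity-profile perturbation.
#' @param participant_speed_sd Between-participant s.d. of the multiplicative
#'   peak-speed factor.
#' @param reaction_time_s Delay between go tone and movement onset (s).
#' @return An object of class `imk_genspec`.
#' @export
generator_spec <- function(seed = 1L, fs = 240,
                           movement_duration_s = 1.2,
                           peak_speed_cm_s = c(shoulder = 25, elbow = 45,
                                               wrist = 70, thumb = 90,
                                               index = 90, middle = 90,
                                               ring = 90, little = 90),
                           actor_imitator_coupling = 0.7,
                           effect_map = list(),
                           spike_rate = 2,
                           spike_amplitude_cm = 10,
                           tms_window_ms = 8,
                           tms_amplitude_cm = 15,
                           noise_sd_cm = 0.02,
                           movement_threshold_cm_s = 12,
                           curve_noise_k = 4L,
                           participant_speed_sd = 0.08,
                           reaction_time_s = 0.15) {
  if (actor_imitator_coupling < 0 || actor_imitator_coupling > 1)
    stop("coupling must lie in [0, 1]", call. = FALSE)
  if (any(peak_speed_cm_s <= 0)) stop("peak speeds must be positive", call. = FALSE)
  miss <- setdiff(TRACKERS, names(peak_speed_cm_s))
  if (length(miss))
    stop("peak_speed_cm_s missing tracker(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (e in effect_map) {
    e$site <- match.arg(e$site, SITES)
    e$stim_time <- match.arg(e$stim_time, STIM_TIMES)
    if (e$factor <= 0) stop("effect factors must be positive", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), fs = fs,
         movement_duration_s = movement_duration_s,
         peak_speed_cm_s = peak_speed_cm_s,
         actor_imitator_coupling = actor_imitator_coupling,
         effect_map = effect_map, spike_rate = spike_rate,
         spike_amplitude_cm = spike_amplitude_cm,
         tms_window_ms = tms_window_ms, tms_amplitude_cm = tms_amplitude_cm,
         noise_sd_cm = noise_sd_cm,
         movement_threshold_cm_s = movement_threshold_cm_s,
         curve_noise_k = as.integer(curve_noise_k),
         participant_speed_sd = participant_speed_sd,
         reaction_time_s = reaction_time_s),
    class = "imk_genspec"
  )
}

effect_factor_for <- function(spec, condition, tracker) {
  f <- 1
  for (e in spec$effect_map) {
    if (identical(e$site, condition$site) &&
        identical(e$stim_time, condition$stim_time) &&
        tracker %in% e$trackers) f <- f * e$factor
  }
  f
}

# Noiseless segmentation of the canonical profile: indices (1-based, on an
# n-point movement grid) of onset (first speed >= thr) and completion (first
# sample after the peak with speed < thr).
bell_segment <- function(n, peak, shape, thr) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  tau <- seq(0, 1, length.out = n)
  v <- peak * stats::dbeta(tau, shape[1], shape[2]) / bell_peak(shape)
  on <- which(v >= thr)[1]
  pk <- which.max(v)
  below <- which(v[(pk + 1):n] < thr)
  off <- if (length(below)) pk + below[1] else n
  list(onset = on, offset = off, v0 = v)
}

# Sample-grid variance of the canonical normalized profile resampled to 120
# points over its supra-threshold segment. Used for closed-form coupling
# attenuation: two curves sharing the deterministic profile with independent
# additive perturbations of variance eps^2 correlate at
# r = V_b / (V_b + eps^2), so eps^2 = V_b (1 - r) / r.
coupling_eps <- function(coupling, n, peak, shape, thr) {
  if (coupling >= 1) return(0)
  if (coupling <= 0) stop("coupling 0 is not attainable: the shared profile is deterministic",
                          call. = FALSE)
  seg <- bell_segment(n, peak, shape, thr)
  b120 <- resample_linear(seg$v0[seg$onset:seg$offset] / max(seg$v0), 120)
  vb <- stats::var(b120)
  sqrt(vb * (1 - coupling) / coupling)
}

# Smooth zero-endpoint perturbation over the movement's supra-threshold
# segment, expressed in segment-relative time u in [0,1]:
# g(u) = sum_k z_k sin(k pi u) / sqrt(K v_k), with v_k the sample variance of
# the k-th component over the grid, so the grid variance of g is 1 in
# expectation. Content is < fs * K / (2 * segment length) Hz, i.e. well under
# the 12 Hz analysis cut-off for default parameters.
curve_noise <- function(u, k) {
  z <- stats::rnorm(k)
  g <- numeric(length(u))
  for (kk in seq_len(k)) {
    s <- sin(kk * pi * u)
    vs <- stats::var(s)
    if (is.finite(vs) && vs > 0) g <- g + z[kk] * s / sqrt(k * vs)
  }
  g
}

# One movement's speed profile: canonical bell plus calibrated smooth
# perturbation confined to the supra-threshold segment (so the noiseless
# threshold crossings delimit every realization identically).
simulate_speed_profile <- function(n, peak, shape, eps, k_noise, thr) {
  seg <- bell_segment(n, peak, shape, thr)
  v <- seg$v0
  if (eps > 0) {
    idx <- seg$onset:seg$offset
    m <- length(idx)
    u <- (idx - seg$onset) / (seg$offset - seg$onset)
    # Perturbation supported on the middle 80% of the segment (so it
    # vanishes near the threshold crossings, which therefore stay put),
    # with zero in-sample covariance with the canonical profile and exactly
    # unit grid variance: the closed-form attenuation then holds in-sample.
    phi <- pmin(pmax((u - 0.1) / 0.8, 0), 1)
    S <- vapply(seq_len(k_noise), function(kk) sin(kk * pi * phi), numeric(m))
    b <- seg$v0[idx] / peak
    w <- drop(crossprod(sweep(S, 2, colMeans(S)), b - mean(b))) / (m - 1)
    N <- qr.Q(qr(cbind(w, diag(length(w)))))[, -1, drop = FALSE]
    M <- crossprod(N, stats::cov(S) %*% N)
    L <- chol((M + t(M)) / 2)
    z <- stats::rnorm(ncol(N))
    cvec <- N %*% backsolve(L, z / sqrt(sum(z^2)))
    g <- as.vector(S %*% cvec)
    v[idx] <- v[idx] + peak * eps * g
    v[v < 0] <- 0
  }
  v
}

# Integrate a speed profile into a 3-D position path along a unit direction.
speed_to_path <- function(v, fs, start, direction) {
  s <- cumtrapz_fs(v, fs)
  sweep(outer(s, direction), 2, start, `+`)
}

random_unit3 <- function() {
  repeat {
    d <- stats::rnorm(3)
    nr <- sqrt(sum(d^2))
    if (nr > 1e-8) return(d / nr)
  }
}

tracker_rest_positions <- function() {
  base <- rbind(shoulder = c(0, 0, 40), elbow = c(5, 12, 25),
                wrist = c(10, 22, 12), thumb = c(12, 26, 10),
                index = c(13, 28, 11), middle = c(13.5, 28.5, 11.5),
                ring = c(13, 29, 11), little = c(12.5, 29.5, 10.5))
  mirror <- sweep(base, 2, c(1, -1, 1), `*`)
  list(imitator = base, actor = sweep(mirror, 2, c(0, 76, 0), `+`))
}

#' Generate one synthetic actor-imitator trial
#'
#' Builds all 16 trajectories over the full trial timeline. Both persons'
#' primary movements follow smooth bell-shaped speed profiles (the
#' minimum-jerk / symmetric-Beta family) along a random 3-D direction, with
#' Gaussian position noise. The imitator's profile shares the actor's
#' canonical curve with an independent smooth perturbation calibrated so the
#' expected correlation of the segmented, resampled speed curves equals the
#' spec's coupling. Condition effects from `effect_map` multiply the
#' imitator's peak speed in the targeted trackers by reshaping the profile
#' (same amplitude and duration, peakier bell). Single-sample spikes and
#' stimulation-locked artifact deflections are injected at known locations,
#' returned as ground truth.
#'
#' @param spec An `imk_genspec`.
#' @param condition Named list with `site`, `stim_time`, `meaning`,
#'   `effector`.
#' @param participant_id Participant identifier (also seeds the
#'   participant-level speed factor).
#' @param session Session number.
#' @param trial_index Index used to derive the trial's random stream from
#'   the master seed.
#' @return An `imk_trial` with attribute `"ground_truth"`: a list with
#'   per-channel injected spike indices, artifact pulse times and window
#'   samples, per-person movement onsets/durations, and the per-tracker
#'   peak-velocity factors applied.
#' @export
generate_trial <- function(spec, condition, participant_id = 1L,
                           session = 1L, trial_index = 1L) {
  condition$site <- match.arg(condition$site, SITES)
  condition$stim_time <- match.arg(condition$stim_time, STIM_TIMES)
  condition$meaning <- match.arg(condition$meaning, MEANINGS)
  condition$effector <- match.arg(condition$effector, EFFECTORS)
  fs <- spec$fs
  tl <- trial_timeline(stim_condition = condition$stim_time)
  trial_dur <- tl$imitator_hold_end_s + 0.5
  n_total <- round(trial_dur * fs) + 1L
  t_axis <- (seq_len(n_total) - 1) / fs

  # participant-level speed factor: deterministic in participant_id only
  set.seed(derive_seed(spec$seed, participant_id, 0L))
  p_speed <- exp(stats::rnorm(1, 0, spec$participant_speed_sd))
  set.seed(derive_seed(spec$seed, participant_id * 1000L + session,
                       trial_index))

  n_mov <- round(spec$movement_duration_s * fs) + 1L
  rest <- tracker_rest_positions()
  onset_s <- c(actor = tl$actor_go_tone_s + spec$reaction_time_s,
               imitator = tl$imitator_go_tone_s + spec$reaction_time_s)
  thr <- spec$movement_threshold_cm_s

  gt_spikes <- list()
  gt_factors <- stats::setNames(numeric(length(TRACKERS)), TRACKERS)
  trajs <- list()
  for (tracker in TRACKERS) {
    base_peak <- spec$peak_speed_cm_s[[tracker]] * p_speed
    f <- effect_factor_for(spec, condition, tracker)
    gt_factors[tracker] <- f
    eps <- coupling_eps(spec$actor_imitator_coupling, n_mov, base_peak,
                        c(3, 3), thr)
    direction <- random_unit3()
    for (person in PERSONS) {
      peak <- base_peak
      shape <- c(3, 3)
      if (person == "imitator" && f != 1) {
        peak <- base_peak * f
        shape <- shape_for_peak_factor(f)
      }
      v <- simulate_speed_profile(n_mov, peak, shape,
                                  if (spec$actor_imitator_coupling < 1) eps else 0,
                                  spec$curve_noise_k, thr)
      start <- rest[[person]][tracker, ]
      path <- speed_to_path(v, fs, start, direction)
      xyz <- matrix(rep(start, each = n_total), n_total, 3)
      i0 <- round(onset_s[[person]] * fs) + 1L
      i1 <- min(i0 + n_mov - 1L, n_total)
      xyz[i0:i1, ] <- path[seq_len(i1 - i0 + 1L), ]
      if (i1 < n_total) xyz[(i1 + 1L):n_total, ] <-
        matrix(rep(path[n_mov, ], each = n_total - i1), n_total - i1, 3)
      if (person == "actor") {
        # return movement to the start point after the hold
        r0 <- round((tl$actor_hold_end_s + spec$reaction_time_s) * fs) + 1L
        r1 <- min(r0 + n_mov - 1L, n_total)
        if (r1 > r0) {
          vr <- simulate_speed_profile(n_mov, base_peak, c(3, 3), 0,
                                       spec$curve_noise_k, thr)
          # scale so the return lands exactly on the start point
          d_out <- sqrt(sum((path[n_mov, ] - start)^2))
          vr <- vr * d_out / cumtrapz_fs(vr, fs)[n_mov]
          back <- speed_to_path(vr, fs, path[n_mov, ], -direction)
          xyz[r0:r1, ] <- back[seq_len(r1 - r0 + 1L), ]
          if (r1 < n_total) xyz[(r1 + 1L):n_total, ] <-
            matrix(rep(start, each = n_total - r1), n_total - r1, 3)
        }
      }
      if (spec$noise_sd_cm > 0)
        xyz <- xyz + matrix(stats::rnorm(3 * n_total, 0, spec$noise_sd_cm),
                            n_total, 3)
      angles <- matrix(rep(stats::runif(3, -90, 90), each = n_total),
                       n_total, 3)
      trajs[[paste(person, tracker, sep = ".")]] <-
        trajectory(tracker, person, fs, xyz, angles)
    }
  }

  # single-sample electromagnetic spikes at known locations
  n_spikes <- stats::rpois(1, spec$spike_rate)
  channels <- trial_channel_names()
  for (ch in channels) gt_spikes[[ch]] <- integer(0)
  if (n_spikes > 0) {
    for (s in seq_len(n_spikes)) {
      ch <- sample(channels, 1)
      idx <- sample(10:(n_total - 10), 1)
      ax <- sample(1:3, 1)
      trajs[[ch]]$xyz[idx, ax] <- trajs[[ch]]$xyz[idx, ax] +
        spec$spike_amplitude_cm * sample(c(-1, 1), 1)
      gt_spikes[[ch]] <- sort(unique(c(gt_spikes[[ch]], idx)))
    }
  }

  # stimulation-locked artifact windows (all channels, half-sine deflection)
  pulses <- pulse_times(tl$stim_onset_s, tl$stim_rate_hz, tl$stim_duration_s)
  gt_windows <- integer(0)
  if (length(pulses) && spec$tms_amplitude_cm > 0) {
    half <- max(1L, round(spec$tms_window_ms / 2 / 1000 * fs))
    for (p in pulses) {
      c0 <- round(p * fs) + 1L
      win <- max(1L, c0 - half):min(n_total, c0 + half)
      bump <- spec$tms_amplitude_cm * sin(seq(0, pi, length.out = length(win)))
      for (ch in channels) {
        ax <- ((c0 + match(ch, channels)) %% 3) + 1L
        trajs[[ch]]$xyz[win, ax] <- trajs[[ch]]$xyz[win, ax] + bump
      }
      gt_windows <- union(gt_windows, win)
    }
  }

  out <- trial(trajs, tl, condition, participant_id = participant_id,
               session = session, artifact_onsets_s = pulses)
  attr(out, "ground_truth") <- list(
    spikes = gt_spikes, pulse_times_s = pulses,
    artifact_samples = sort(gt_windows),
    movement_onset_s = onset_s, movement_duration_s = spec$movement_duration_s,
    peak_factors = gt_factors, participant_speed_factor = p_speed)
  out
}

#' Generate a full synthetic experiment
#'
#' Produces `n_participants x sessions x trials_per_session` trials with
#' counterbalanced condition assignment: one stimulation site per session
#' (Latin-square order across participants), and within each session a
#' balanced crossing of stimulation time (observation/imitation), meaning
#' (meaningful/meaningless, equal halves) and effector (hand/finger),
#' presented in meaning-blocked order. Per-trial seeds derive
#' deterministically from the master seed.
#'
#' @param spec An `imk_genspec`.
#' @param design An `imk_design`.
#' @param out_dir Optional directory; when given, every trial is written via
#'   [write_trial()] and a `manifest.json` is emitted.
#' @return The manifest data frame (columns `participant_id`, `session`,
#'   `site`, `stim_time`, `meaning`, `effector`, `trial_index`, `path`), with
#'   attribute `"trials"` holding the `imk_trial` list when `out_dir` is
#'   `NULL`.
#' @export
generate_experiment <- function(spec, design, out_dir = NULL) {
  if (!inherits(design, "imk_design")) stop("need an `imk_design`", call. = FALSE)
  nt <- design$trials_per_session
  if (nt %% 8L != 0L)
    stop("trials_per_session must be a multiple of 8 for balanced crossing",
         call. = FALSE)
  rows <- list(); trials <- list(); k <- 0L
  for (p in seq_len(design$n_participants)) {
    site_order <- SITES[((p - 1L + 0:2) %% 3L) + 1L]  # Latin square
    for (s in seq_len(design$sessions_per_participant)) {
      site <- site_order[s]
      cells <- expand.grid(stim_time = STIM_TIMES, effector = EFFECTORS,
                           meaning = MEANINGS, stringsAsFactors = FALSE)
      cells <- cells[rep(seq_len(nrow(cells)), each = nt / 8L), ]
      set.seed(derive_seed(spec$seed, 500000L + p, s))
      # meaning-blocked presentation, randomized within block
      blocks <- split(cells, cells$meaning)
      blocks <- lapply(blocks, function(b) b[sample(nrow(b)), ])
      if (p %% 2L == 0L) blocks <- rev(blocks)
      cells <- do.call(rbind, blocks)
      for (i in seq_len(nrow(cells))) {
        k <- k + 1L
        cond <- list(site = site, stim_time = cells$stim_time[i],
                     meaning = cells$meaning[i], effector = cells$effector[i])
        tr <- generate_trial(spec, cond, participant_id = p, session = s,
                             trial_index = i)
        rel <- sprintf("p%02d_s%d_t%02d", p, s, i)
        rows[[k]] <- data.frame(participant_id = p, session = s,
                                site = cond$site, stim_time = cond$stim_time,
                                meaning = cond$meaning,
                                effector = cond$effector,
                                trial_index = i, path = rel)
        if (is.null(out_dir)) trials[[k]] <- tr
        else write_trial(tr, file.path(out_dir, rel))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  } else {
    attr(manifest, "trials") <- trials
  }
  manifest
}

#' Generate a synthetic finger-thumb opposition recording
#'
#' The thumb travels between the four fingertips in the back-and-forth order
#' index, middle, ring, little, ring, middle, ... touching one fingertip at
#' each ground-truth touch time (thumb-fingertip distance dips to the noise
#' floor there); fingertips hold their rest positions with a small
#' oscillation. The recording spans three 5 s epochs (pre-stimulation,
#' stimulation, post-stimulation) with the stimulation train at 3 Hz from
#' 5.00 s.
#'
#' @param spec An `imk_genspec`.
#' @param duration_s Total duration (s), at least 3 epochs.
#' @param iti_ms Target inter-touch interval (ms).
#' @param iti_jitter_ms Half-width of the uniform jitter on each interval
#'   (ms).
#' @param participant_id Participant identifier.
#' @param session Session number.
#' @return A list: `trajectories` (named `imk_trajectory` list: thumb plus
#'   four fingers), `touch_times_s`, `touch_digits`, `epochs` (an
#'   [epoch_spec()]), `pulse_times_s`.
#' @export
generate_opposition <- function(spec, duration_s = 15, iti_ms = 350,
                                iti_jitter_ms = 0, participant_id = 1L,
                                session = 1L) {
  fs <- spec$fs
  if (duration_s < 15) stop("opposition recording must cover the 3 x 5 s epochs",
                            call. = FALSE)
  if (iti_ms < 4000 / fs)
    stop("iti_ms too small for the sampling rate", call. = FALSE)
  set.seed(derive_seed(spec$seed, 900000L + participant_id, session))
  n <- round(duration_s * fs) + 1L
  t_axis <- (seq_len(n) - 1) / fs

  finger_pos <- rbind(index = c(0, 0, 0), middle = c(2, 0.5, 0),
                      ring = c(4, 0.5, 0), little = c(6, 0, 0))
  cycle <- c("index", "middle", "ring", "little", "ring", "middle")

  t0 <- iti_ms / 1000
  touches <- numeric(0)
  tt <- t0
  while (tt <= duration_s - 0.05) {
    touches <- c(touches, tt)
    jit <- if (iti_jitter_ms > 0) stats::runif(1, -iti_jitter_ms, iti_jitter_ms) / 1000 else 0
    tt <- tt + iti_ms / 1000 + jit
  }
  digits <- cycle[((seq_along(touches) - 1) %% length(cycle)) + 1]

  # fingertips first: rest position plus a small vertical oscillation (the
  # fingers are never perfectly still); the thumb must meet the fingertip
  # where it actually is at contact time
  noise_sd <- min(spec$noise_sd_cm, 0.05)
  finger_clean <- list()
  for (f in rownames(finger_pos)) {
    osc <- 0.3 * sin(2 * pi * 1.5 * t_axis + stats::runif(1, 0, 2 * pi))
    xyz <- matrix(rep(finger_pos[f, ], each = n), n, 3)
    xyz[, 3] <- xyz[, 3] + osc
    finger_clean[[f]] <- xyz
  }

  # thumb path: minimum-jerk hops, each with a perpendicular lift arc (so
  # the thumb only dwells near the target briefly), landing on the moving
  # fingertip exactly at each ground-truth touch time; after the last touch
  # the thumb rests where it is
  thumb_start <- c(-2, 1, 1)
  thumb <- matrix(NA_real_, n, 3)
  touch_idx <- round(touches * fs) + 1L
  anchors_t <- c(0, touches, duration_s + 1 / fs)
  anchors_p <- rbind(thumb_start,
                     t(vapply(seq_along(touches), function(k)
                       finger_clean[[digits[k]]][touch_idx[k], ],
                       numeric(3))))
  # after the last touch the thumb lifts off and rests above the hand
  anchors_p <- rbind(anchors_p, anchors_p[nrow(anchors_p), ] + c(0, 0, 1.2))
  lift_cm <- 1.2
  n_seg <- length(anchors_t) - 1L
  for (seg in seq_len(n_seg)) {
    i0 <- round(anchors_t[seg] * fs) + 1L
    i1 <- min(round(anchors_t[seg + 1] * fs) + 1L, n)
    if (i1 <= i0) next
    tau <- seq(0, 1, length.out = i1 - i0 + 1L)
    shape <- minjerk_position(tau)
    for (ax in 1:3)
      thumb[i0:i1, ax] <- anchors_p[seg, ax] +
        (anchors_p[seg + 1, ax] - anchors_p[seg, ax]) * shape
    if (seg < n_seg)  # no lift on the final hold
      thumb[i0:i1, 3] <- thumb[i0:i1, 3] + lift_cm * sin(pi * tau)^2
  }
  thumb[is.na(thumb[, 1]), ] <- rep(anchors_p[nrow(anchors_p), ],
                                    each = sum(is.na(thumb[, 1])))

  trajs <- list()
  trajs[["thumb"]] <- trajectory("thumb", "imitator", fs,
                                 thumb + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3))
  for (f in rownames(finger_pos)) {
    xyz <- finger_clean[[f]] + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
    trajs[[f]] <- trajectory(f, "imitator", fs, xyz)
  }

  list(trajectories = trajs,
       touch_times_s = touches, touch_digits = digits,
       epochs = epoch_spec(),
       pulse_times_s = pulse_times(5.00, 3, 14 / 3))
}
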