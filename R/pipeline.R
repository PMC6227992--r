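#' Pipeline run configuration
#'
#' Bundles every module's parameters with a master seed. All numeric
#' behaviour of [run_pipeline()] is a deterministic function of this object.
#'
#' @param generator An `imk_genspec`.
#' @param design An `imk_design`.
#' @param spike,smooth,filt,segmentation,tms_window_ms Preprocessing and
#'   segmentation parameter objects.
#' @param cluster_permutations Permutation count for cluster tests.
#' @param cluster_contrast Character pair of sites compared in the
#'   per-tracker cluster tests.
#' @param family_alpha Family alpha divided over the 8 trackers for the
#'   accuracy ANOVAs.
#' @return An object of class `imk_config`.
#' @export
run_config <- function(generator = generator_spec(),
                       design = experiment_design(),
                       spike = spike_params(), smooth = smooth_params(),
                       filt = filter_spec(), segmentation = seg_params(),
                       tms_window_ms = 50,
                       cluster_permutations = 10000L,
                       cluster_contrast = c("PMv", "PMd"),
                       family_alpha = 0.05) {
  structure(list(generator = generator, design = design, spike = spike,
                 smooth = smooth, filt = filt, segmentation = segmentation,
                 tms_window_ms = tms_window_ms,
                 cluster_permutations = as.integer(cluster_permutations),
                 cluster_contrast = cluster_contrast,
                 family_alpha = family_alpha),
            class = "imk_config")
}

# FNV-1a hash of a string, for provenance records
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit FNV prime multiply (16777619 = 2^24 + 403), exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Per-trial peak-parameter records for a set of trials
#'
#' Segments every imitator tracker of every trial and tabulates PV, PA, PD
#' plus the exclusion flag (excluded trials keep their rows so retention
#' bookkeeping stays explicit).
#'
#' @param trials List of preprocessed `imk_trial` objects.
#' @param params An `imk_seg_params`.
#' @param person Person whose kinematics are extracted.
#' @return Data frame with one row per (trial, tracker) with a movement.
#' @export
kinematic_records <- function(trials, params = seg_params(),
                              person = "imitator") {
  rows <- list(); k <- 0L
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    kin <- trial_kinematics(tr, person, params)
    for (tracker in names(kin)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = tr$participant_id, session = tr$session,
        site = tr$condition$site, stim_time = tr$condition$stim_time,
        meaning = tr$condition$meaning, effector = tr$condition$effector,
        trial_index = i, tracker = tracker,
        PV = kin[[tracker]]$peaks$PV, PA = kin[[tracker]]$peaks$PA,
        PD = kin[[tracker]]$peaks$PD,
        excluded = isTRUE(tr$excluded),
        exclusion_reason = if (is.na(tr$exclusion_reason)) "" else tr$exclusion_reason)
    }
  }
  if (!k) stop("no segmentable movements in any trial", call. = FALSE)
  do.call(rbind, rows)
}

#' Participant-mean resampled curves for one cell
#'
#' Averages each participant's retained-trial normalized curves for one
#' tracker within a condition cell, the unit of analysis of the
#' cluster-length permutation test.
#'
#' @param trials List of preprocessed, exclusion-flagged `imk_trial`s.
#' @param tracker Tracker name.
#' @param site,stim_time Optional condition filters (`NULL` = any).
#' @param person Person whose curves are used.
#' @param params An `imk_seg_params`.
#' @return Matrix participants x 120, rownames = participant ids (ordered).
#' @export
participant_mean_curves <- function(trials, tracker, site = NULL,
                                    stim_time = NULL, person = "imitator",
                                    params = seg_params()) {
  acc <- list()
  for (tr in trials) {
    if (isTRUE(tr$excluded)) next
    if (!is.null(site) && tr$condition$site != site) next
    if (!is.null(stim_time) && tr$condition$stim_time != stim_time) next
    kin <- trial_kinematics(tr, person, params)
    if (is.null(kin[[tracker]])) next
    pid <- as.character(tr$participant_id)
    acc[[pid]] <- rbind(acc[[pid]], as.numeric(kin[[tracker]]$curve))
  }
  if (!length(acc)) stop("no retained curves for this cell", call. = FALSE)
  ids <- sort(names(acc))
  out <- t(vapply(acc[ids], colMeans, numeric(120)))
  rownames(out) <- ids
  out
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Simulate, preprocess, flag exclusions, extract kinematics and accuracy,
#' run the per-tracker cluster-length permutation test on the configured
#' site contrast, and (when the design crosses all factor levels) the
#' four-way repeated-measures ANOVA of mean Fisher-z per tracker. Re-running
#' with the same config reproduces every number bit for bit.
#'
#' @param config An `imk_config`.
#' @param out_dir Optional output directory for CSV/JSON stage outputs and
#'   the provenance record.
#' @return A list: `manifest`, `retention` (counts and reasons),
#'   `kinematics` (records), `accuracy` (records), `cell_means`, `clusters`
#'   (per tracker `imk_cluster_result`), `anova` (per tracker, possibly
#'   `NULL`), `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "imk_config")) stop("need an `imk_config`", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- generate_experiment(config$generator, config$design)
  trials <- attr(manifest, "trials")
  attr(manifest, "trials") <- NULL

  trials <- lapply(trials, preprocess_trial, spike = config$spike,
                   smooth = config$smooth, filt = config$filt,
                   tms_window_ms = config$tms_window_ms)
  trials <- lapply(trials, apply_exclusions, params = config$segmentation)

  reasons <- vapply(trials, function(t)
    if (isTRUE(t$excluded)) t$exclusion_reason else "retained", character(1))
  retention <- as.list(table(reasons))
  retention$total <- length(trials)
  retention$retained_fraction <-
    sum(reasons == "retained") / length(trials)

  kin <- kinematic_records(trials, config$segmentation)
  acc <- accuracy_records(trials, config$segmentation)
  means <- condition_means(acc)

  cl_spec <- cluster_spec(
    n_participants = config$design$n_participants,
    n_permutations = config$cluster_permutations,
    seed = derive_seed(config$generator$seed, 42L, 0L))
  clusters <- list()
  for (tracker in TRACKERS) {
    a <- try(participant_mean_curves(trials, tracker,
                                     site = config$cluster_contrast[1]),
             silent = TRUE)
    b <- try(participant_mean_curves(trials, tracker,
                                     site = config$cluster_contrast[2]),
             silent = TRUE)
    if (inherits(a, "try-error") || inherits(b, "try-error")) next
    common <- intersect(rownames(a), rownames(b))
    if (length(common) < 3) next
    sp <- cl_spec; sp$n_participants <- length(common)
    sp$df <- length(common) - 1L
    sp$t_crit <- stats::qt(1 - sp$alpha_samplewise / 2, sp$df)
    clusters[[tracker]] <- cluster_test(a[common, , drop = FALSE],
                                        b[common, , drop = FALSE], sp)
  }

  anova_res <- NULL
  has_full <- length(unique(means$site)) == 3 &&
    length(unique(means$stim_time)) == 2 &&
    length(unique(means$meaning)) == 2 &&
    length(unique(means$effector)) == 2
  if (has_full) {
    anova_res <- list()
    for (tracker in unique(means$tracker)) {
      sub <- means[means$tracker == tracker, , drop = FALSE]
      res <- try(rm_anova(sub, "mean_Z", "participant_id",
                          c("site", "stim_time", "meaning", "effector")),
                 silent = TRUE)
      if (!inherits(res, "try-error")) anova_res[[tracker]] <- res
    }
  }

  cfg_json <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  provenance <- list(
    config_hash = fnv1a(as.character(cfg_json)),
    seed = config$generator$seed,
    package_version = as.character(utils::packageVersion("imikin")),
    n_trials = length(trials), n_retained = sum(reasons == "retained"),
    n_kinematic_records = nrow(kin), n_accuracy_records = nrow(acc))

  out <- list(manifest = manifest, retention = retention, kinematics = kin,
              accuracy = acc, cell_means = means, clusters = clusters,
              anova = anova_res, provenance = provenance)
  if (!is.null(out_dir)) {
    utils::write.csv(kin, file.path(out_dir, "kinematics.csv"),
                     row.names = FALSE)
    utils::write.csv(acc, file.path(out_dir, "accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(means, file.path(out_dir, "cell_means.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# ---- simulation studies ----------------------------------------------------

# Fast path shared by the calibration and recovery studies: one tracker's
# movement synthesized in speed space and pushed through the package's own
# segmentation / resampling / peak extraction. Profile perturbation gives
# within-participant trial-to-trial curve variability; the participant
# factor scales peak speed.
simulate_trial_curve <- function(n_mov, peak, shape, eps, k_noise, thr,
                                 fs, want_pv = FALSE) {
  v <- simulate_speed_profile(n_mov, peak, shape, eps, k_noise, thr)
  seg <- segment_primary(v, seg_params(movement_threshold_cm_s = thr))
  if (!seg$moved || seg$offset - seg$onset < 2L) return(NULL)
  segment <- v[seg$onset:seg$offset]
  out <- list(curve = as.numeric(resample_normalize(segment)))
  if (want_pv) out$PV <- peak_params(segment, fs)$PV
  out
}

#' Family-wise type-I error of the cluster test on null experiments
#'
#' Generates replicate null experiments (no condition effect anywhere):
#' each participant contributes `trials_per_cell` movements per condition
#' cell drawn from the same generator settings; participant-mean curves are
#' compared with the cluster-length permutation test and a replicate counts
#' as a false positive when any run reaches p < `alpha_cluster`. The
#' returned proportion estimates the family-wise false-positive rate of the
#' whole inference chain.
#'
#' @param n_experiments Number of replicate experiments.
#' @param n_participants Participants per experiment.
#' @param trials_per_cell Trials per participant per condition cell.
#' @param n_permutations Permutations per cluster test.
#' @param alpha_cluster Cluster-level significance threshold.
#' @param spec An `imk_genspec` (its coupling sets the trial-to-trial curve
#'   perturbation).
#' @param seed Seed for the whole study.
#' @return List with `false_positive_rate`, `n_experiments`, `hits`.
#' @export
cluster_type1_study <- function(n_experiments = 500, n_participants = 12,
                                trials_per_cell = 8, n_permutations = 1000,
                                alpha_cluster = 0.05,
                                spec = generator_spec(), seed = 1L) {
  fs <- spec$fs
  n_mov <- round(spec$movement_duration_s * fs) + 1L
  thr <- spec$movement_threshold_cm_s
  base_peak <- spec$peak_speed_cm_s[["index"]]
  hits <- logical(n_experiments)
  for (e in seq_len(n_experiments)) {
    set.seed(derive_seed(seed, 70000L + e, 0L))
    cells <- vector("list", 2)
    for (cond in 1:2) {
      mat <- matrix(NA_real_, n_participants, 120)
      for (p in seq_len(n_participants)) {
        pk <- base_peak * exp(stats::rnorm(1, 0, spec$participant_speed_sd))
        eps <- coupling_eps(spec$actor_imitator_coupling, n_mov, pk, c(3, 3), thr)
        cs <- matrix(NA_real_, trials_per_cell, 120)
        for (tr in seq_len(trials_per_cell)) {
          sim <- simulate_trial_curve(n_mov, pk, c(3, 3), eps, spec$curve_noise_k,
                                      thr, fs)
          cs[tr, ] <- sim$curve
        }
        mat[p, ] <- colMeans(cs)
      }
      cells[[cond]] <- mat
    }
    sp <- cluster_spec(n_participants, n_permutations = n_permutations,
                       seed = derive_seed(seed, 80000L + e, 0L))
    res <- cluster_test(cells[[1]], cells[[2]], sp)
    hits[e] <- nrow(res$runs) > 0 && any(res$runs$p < alpha_cluster)
  }
  list(false_positive_rate = mean(hits), n_experiments = n_experiments,
       hits = sum(hits))
}

#' Recovery of an injected digit peak-velocity effect
#'
#' Generates replicate experiments in which the imitator's digit peak
#' velocity is raised by `factor` in one condition cell (the profile is
#' reshaped at fixed amplitude and duration, the generator's realization of
#' a peak-velocity effect). Each replicate runs the package's own
#' segmentation, peak extraction and cluster-length permutation test on the
#' mean digit curves, and checks (a) the mean digit PV is elevated in the
#' effect cell and (b) a significant run overlaps the PV region of the
#' grand-mean curve.
#'
#' @param n_experiments Number of replicate experiments.
#' @param n_participants Participants per experiment.
#' @param trials_per_cell Trials per participant per cell.
#' @param factor Multiplicative peak-velocity factor in the effect cell.
#' @param n_permutations Permutations per cluster test.
#' @param alpha_cluster Cluster-level significance threshold.
#' @param spec An `imk_genspec`.
#' @param seed Seed for the whole study.
#' @return List with `recovery_rate` (proportion of replicates meeting both
#'   checks), `pv_elevated_rate`, `significant_run_rate`, `mean_pv_ratio`.
#' @export
effect_recovery_study <- function(n_experiments = 100, n_participants = 12,
                                  trials_per_cell = 32, factor = 1.15,
                                  n_permutations = 1000,
                                  alpha_cluster = 0.05,
                                  spec = generator_spec(), seed = 1L) {
  fs <- spec$fs
  n_mov <- round(spec$movement_duration_s * fs) + 1L
  thr <- spec$movement_threshold_cm_s
  shape_eff <- shape_for_peak_factor(factor)
  ok_both <- ok_pv <- ok_run <- logical(n_experiments)
  pv_ratio <- numeric(n_experiments)
  for (e in seq_len(n_experiments)) {
    set.seed(derive_seed(seed, 30000L + e, 0L))
    cellA <- cellB <- matrix(NA_real_, n_participants, 120)
    pvA <- pvB <- numeric(n_participants)
    for (p in seq_len(n_participants)) {
      pf <- exp(stats::rnorm(1, 0, spec$participant_speed_sd))
      for (cond in c("effect", "baseline")) {
        curves <- matrix(NA_real_, trials_per_cell, 120)
        pv_tr <- numeric(trials_per_cell)
        for (tr in seq_len(trials_per_cell)) {
          digit_curves <- matrix(NA_real_, length(DIGITS), 120)
          digit_pv <- numeric(length(DIGITS))
          for (d in seq_along(DIGITS)) {
            pk0 <- spec$peak_speed_cm_s[[DIGITS[d]]] * pf
            pk <- if (cond == "effect") pk0 * factor else pk0
            sa <- if (cond == "effect") shape_eff else c(3, 3)
            eps <- coupling_eps(spec$actor_imitator_coupling, n_mov, pk, sa,
                                thr)
            sim <- simulate_trial_curve(n_mov, pk, sa, eps,
                                        spec$curve_noise_k, thr, fs,
                                        want_pv = TRUE)
            digit_curves[d, ] <- sim$curve
            digit_pv[d] <- sim$PV
          }
          curves[tr, ] <- colMeans(digit_curves)
          pv_tr[tr] <- mean(digit_pv)
        }
        if (cond == "effect") { cellA[p, ] <- colMeans(curves); pvA[p] <- mean(pv_tr) }
        else { cellB[p, ] <- colMeans(curves); pvB[p] <- mean(pv_tr) }
      }
    }
    sp <- cluster_spec(n_participants, n_permutations = n_permutations,
                       seed = derive_seed(seed, 40000L + e, 0L))
    res <- cluster_test(cellA, cellB, sp)
    grand <- colMeans(rbind(cellA, cellB))
    sig <- res$runs[res$runs$p < alpha_cluster, , drop = FALSE]
    hit_run <- FALSE
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig)))
        if ("PV" %in% overlap_with_peaks(sig[i, ], grand)) hit_run <- TRUE
    }
    ok_pv[e] <- mean(pvA) > mean(pvB)
    ok_run[e] <- hit_run
    ok_both[e] <- ok_pv[e] && hit_run
    pv_ratio[e] <- mean(pvA) / mean(pvB)
  }
  list(recovery_rate = mean(ok_both), pv_elevated_rate = mean(ok_pv),
       significant_run_rate = mean(ok_run), mean_pv_ratio = mean(pv_ratio))
}
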