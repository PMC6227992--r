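test_that("speed3d matches closed-form speeds", {
  expect_equal(speed3d(make_traj(matrix(3, 50, 3))), rep(0, 50))
  tr <- line_traj(60, v = c(6, 8, 0))
  expect_equal(speed3d(tr), rep(10, 60), tolerance = 1e-10)
  # circular motion radius r, angular rate w -> speed r*w
  fs <- 240; t <- (0:499) / fs; r <- 5; w <- 2 * pi * 1.5
  circ <- make_traj(cbind(r * cos(w * t), r * sin(w * t), 0 * t), fs = fs)
  sp <- speed3d(circ)[10:490]
  expect_equal(max(abs(sp - r * w)) / (r * w), 0, tolerance = 1e-3)
})

test_that("segmentation finds the analytic threshold crossings of a bell", {
  D <- 30; T_s <- 1; fs <- 240
  tr <- minjerk_traj(D, T_s, fs)
  sp <- speed3d(tr)
  seg <- segment_primary(sp)
  # analytic crossings of 30 D/T tau^2 (1-tau)^2 = 12 cm/s
  f <- function(tau) D / T_s * minjerk_speed(tau) - 12
  on_tau <- uniroot(f, c(0.01, 0.5))$root
  off_tau <- uniroot(f, c(0.5, 0.99))$root
  expect_lte(abs(seg$onset - (round(on_tau * T_s * fs) + 1)), 1)
  expect_lte(abs(seg$offset - (round(off_tau * T_s * fs) + 1)), 1)
  expect_true(seg$onset < seg$peak && seg$peak <= seg$offset)
  expect_true(seg$complete)

  # all-below-threshold series -> no-movement flag
  expect_false(segment_primary(rep(5, 100))$moved)

  # plateau: offset at first sub-threshold sample after the peak
  v <- c(0, 5, 20, 80, 40, 13, 11, 11, 14, 5)
  seg2 <- segment_primary(v)
  expect_equal(seg2$onset, 3)
  expect_equal(seg2$peak, 4)
  expect_equal(seg2$offset, 7)
})

test_that("resample_normalize: 120 samples, unit peak, idempotent", {
  out <- resample_normalize(rep(7, 30))
  expect_length(out, 120)
  expect_equal(as.numeric(out), rep(1, 120))

  # already-120 segment: values unchanged up to normalization
  v <- runif(120, 1, 5)
  expect_equal(as.numeric(resample_normalize(v)), v / max(v))

  # half-sine of any length peaks at the middle output sample
  for (n in c(37, 120, 301)) {
    hs <- sin(pi * seq(0, 1, length.out = n))
    out <- resample_normalize(hs)
    expect_equal(max(out), 1)
    expect_lte(abs(which.max(out) - 60.5), 1.5)
  }

  # idempotence within 1e-9
  v <- minjerk_speed(seq(0, 1, length.out = 87))
  once <- resample_normalize(v)
  twice <- resample_normalize(as.numeric(once))
  expect_equal(as.numeric(twice), as.numeric(once), tolerance = 1e-9)

  expect_error(resample_normalize(rep(0, 50)), "degenerate")
  expect_error(resample_normalize(3), "at least 2")
})

test_that("peak parameters match closed forms and brute-force scans", {
  D <- 40; T_s <- 1.2; fs <- 240
  tau <- seq(0, 1, length.out = round(T_s * fs) + 1)
  v <- D / T_s * minjerk_speed(tau)
  pk <- peak_params(v, fs)
  expect_equal(pk$PV, 1.875 * D / T_s, tolerance = 0.005)
  # symmetric bell: |PA| = |PD| up to discretization
  expect_equal(abs(pk$PA), abs(pk$PD), tolerance = 0.01 * abs(pk$PA))

  # monotone ramp: PV at final sample, PD ~ 0
  ramp <- seq(0, 50, length.out = 100)
  pk2 <- peak_params(ramp, fs)
  expect_equal(pk2$PV, 50)
  expect_gte(pk2$PD, 0 - 1e-9)

  # brute-force scan of the discrete derivative on random fixtures
  set.seed(8)
  for (i in 1:20) {
    v <- abs(cumsum(rnorm(50)))
    pk3 <- peak_params(v, fs)
    acc <- deriv1(v, fs)
    expect_equal(pk3$PV, max(v))
    expect_equal(pk3$PA, max(acc))
    expect_equal(pk3$PD, min(acc))
    expect_true(pk3$PA >= 0 && pk3$PD <= pk3$PA)
  }
})

test_that("exclusion rules fire in fixed order with a single reason", {
  spec <- quick_genspec(seed = 17)
  tr <- generate_trial(spec, default_condition(), 1, trial_index = 1)
  trp <- preprocess_trial(tr)
  clean <- apply_exclusions(trp)
  expect_false(clean$excluded)

  # overspeed: one wrist sample pushed past 250 cm/s
  fast <- trp
  i <- round(fast$timeline$imitator_go_tone_s * 240) + 120
  fast$trajectories[["imitator.wrist"]]$xyz[i, 1] <-
    fast$trajectories[["imitator.wrist"]]$xyz[i - 1, 1] + 260 / 240 * 2
  out <- apply_exclusions(fast)
  expect_true(out$excluded)
  expect_equal(out$exclusion_reason, "overspeed")

  # premature start: movement onset before the imitator go tone
  early <- trp
  j <- round((early$timeline$imitator_go_tone_s - 0.05) * 240) + 1
  seg <- j:(j + 30)
  early$trajectories[["imitator.index"]]$xyz[seg, 1] <-
    early$trajectories[["imitator.index"]]$xyz[seg, 1] +
    cumsum(rep(20 / 240, length(seg)))
  out2 <- apply_exclusions(early)
  expect_true(out2$excluded)
  expect_equal(out2$exclusion_reason, "premature_start")
})

test_that("retention bookkeeping: retained + excluded = total, one reason each", {
  spec <- quick_genspec(seed = 23)
  design <- experiment_design(2, 1, 8)
  man <- generate_experiment(spec, design)
  trials <- attr(man, "trials")
  trials <- lapply(trials, preprocess_trial)
  trials <- lapply(trials, apply_exclusions)
  flags <- vapply(trials, function(t) isTRUE(t$excluded), logical(1))
  reasons <- vapply(trials, function(t)
    if (isTRUE(t$excluded)) t$exclusion_reason else NA_character_,
    character(1))
  expect_equal(sum(flags) + sum(!flags), length(trials))
  expect_true(all(is.na(reasons[!flags])))
  expect_true(all(reasons[flags] %in%
                    c("premature_start", "late_finish", "overspeed")))
})

test_that("mean digit parameters average the five digits per cell", {
  rec <- expand.grid(participant_id = 1:2, site = c("PMv", "PMd"),
                     stim_time = "imitation", tracker = TRACKERS,
                     trial_index = 1:2, stringsAsFactors = FALSE)
  rec$PV <- 50
  rec$PV[rec$tracker %in% DIGITS & rec$site == "PMv"] <- 60
  rec$excluded <- FALSE
  out <- mean_digit_params(rec, "PV")
  expect_equal(out$mean_value[out$site == "PMv"], c(60, 60))
  expect_equal(out$mean_value[out$site == "PMd"], c(50, 50))
  # excluded trials are not counted
  rec2 <- rec
  rec2$excluded[rec2$trial_index == 2] <- TRUE
  rec2$PV[rec2$trial_index == 2] <- 999
  out2 <- mean_digit_params(rec2, "PV")
  expect_equal(out2$mean_value[out2$site == "PMv"], c(60, 60))
})
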