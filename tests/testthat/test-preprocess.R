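test_that("spike detection: smooth paths clean, displaced samples flagged", {
  expect_equal(detect_spikes(make_traj(matrix(5, 50, 3))), integer(0))
  t <- (0:199) / 240
  sine <- make_traj(cbind(sin(2 * pi * 2 * t), 0 * t, 0 * t))
  expect_equal(detect_spikes(sine), integer(0))

  # single displaced sample on a linear path: oracle = brute-force z-score
  # of the second-difference series
  tr <- line_traj(100, v = c(24, 0, 0))
  tr$xyz[40, 1] <- tr$xyz[40, 1] + 10
  d2 <- diff(tr$xyz[, 1], differences = 2)
  z <- abs(d2 - mean(d2)) / sd(d2)
  oracle <- which(z > 3) + 1L
  expect_true(40 %in% oracle)
  expect_equal(detect_spikes(tr), oracle)
  expect_error(detect_spikes(line_traj(3)), "at least 5")
})

test_that("spike repair: linear interpolation across three samples either side", {
  tr <- line_traj(30, v = c(24, 0, 0))
  truth <- tr$xyz[, 1]
  tr$xyz[10, 1] <- tr$xyz[10, 1] + 8
  fixed <- repair_spikes(tr, 10L)
  expect_equal(fixed$xyz[, 1], truth, tolerance = 1e-12)

  # boundary spike: window clamped to the nearest valid anchor
  tr2 <- line_traj(30, v = c(24, 0, 0))
  tr2$xyz[2, 1] <- tr2$xyz[2, 1] + 8
  expect_silent(fixed2 <- repair_spikes(tr2, 2L))
  expect_equal(fixed2$xyz[6:30, 1], truth[6:30], tolerance = 1e-12)

  # two spikes 4 samples apart -> one merged window; oracle applies the
  # definition by hand on a 20-sample vector
  x <- seq(0, 19) * 2
  y <- x; y[8] <- y[8] + 50; y[12] <- y[12] + 50
  tr3 <- make_traj(cbind(y, 0 * y, 0 * y))
  merged <- imikin:::merge_windows(c(8L, 12L), 3L, 20L)
  expect_length(merged, 1)
  expect_equal(merged[[1]], c(5L, 15L))
  hand <- y
  hand[5:15] <- y[4] + (y[16] - y[4]) * ((5:15) - 4) / (16 - 4)
  got <- repair_spikes(tr3, c(8L, 12L))
  expect_equal(got$xyz[, 1], hand, tolerance = 1e-12)
})

test_that("local-regression outlier pass flags gross residuals only", {
  tr <- line_traj(80, v = c(24, 0, 0))
  expect_equal(lowess_outliers(tr), integer(0))
  set.seed(1)
  tr$xyz <- tr$xyz + matrix(rnorm(240, 0, 0.01), 80, 3)
  clean_flags <- length(lowess_outliers(tr))
  tr$xyz[33, 2] <- tr$xyz[33, 2] + 0.2  # 20x the noise s.d.
  expect_true(33 %in% lowess_outliers(tr))
  # smoothing an already-repaired series is near-idempotent
  fixed <- repair_spikes(tr, lowess_outliers(tr))
  refl <- lowess_outliers(fixed)
  expect_lte(length(refl), clean_flags + 2)
})

test_that("artifact excision reconstructs cubics exactly and reports runs", {
  t <- (0:299) / 240
  cubic <- 2 + 3 * t - 4 * t^2 + 5 * t^3
  tr <- make_traj(cbind(cubic, 2 * cubic, 0 * t + 1))
  truth <- tr$xyz
  out <- excise_tms_artifacts(tr, onsets_s = c(0.4, 0.8), window_ms = 50)
  expect_equal(out$xyz, truth, tolerance = 1e-9)
  rep <- attr(out, "report")
  expect_equal(rep$n_periods, 2)
  expect_equal(rep$total_samples, sum(rep$period_lengths))
  expect_equal(rep$max_run, max(rep$period_lengths))

  # overlapping windows are merged before interpolation
  out2 <- excise_tms_artifacts(tr, onsets_s = c(0.4, 0.42), window_ms = 50)
  expect_equal(attr(out2, "report")$n_periods, 1)

  # printed sample -> ms conversions at 240 Hz
  expect_equal(samples_to_ms(53, 240, 0), 221)
  expect_equal(samples_to_ms(33, 240, 0), 138)
  expect_equal(samples_to_ms(28, 240, 0), 117)
  expect_equal(samples_to_ms(19, 240, 1), 79.2)

  expect_error(excise_tms_artifacts(tr, onsets_s = 5), "outside")
  expect_error(excise_tms_artifacts(tr, seq(0.05, 1.2, by = 0.05),
                                    window_ms = 2000), "90%")
})

test_that("zero-phase Butterworth: DC exact, gains match the closed form", {
  n <- 400; fs <- 240
  const <- make_traj(matrix(7, n, 3), fs = fs)
  out <- lowpass(const)
  expect_equal(out$xyz, const$xyz, tolerance = 1e-9)

  # two-pass amplitude gain equals the squared single-pass magnitude of the
  # digital design; oracle computed from the coefficients independently
  bt <- signal::butter(4, 12 / (fs / 2))
  gain_at <- function(f_hz) {
    w <- 2 * pi * f_hz / fs
    H <- sum(bt$b * exp(-1i * w * (seq_along(bt$b) - 1))) /
      sum(bt$a * exp(-1i * w * (seq_along(bt$a) - 1)))
    Mod(H)^2
  }
  nl <- 1600
  t <- (seq_len(nl) - 1) / fs
  for (f in c(2, 50)) {
    x <- sin(2 * pi * f * t)
    tr <- make_traj(cbind(x, 0 * x, 0 * x), fs = fs)
    y <- lowpass(tr)$xyz[, 1]
    core <- 400:(nl - 400)
    meas <- max(abs(y[core])) / max(abs(x[core]))
    expect_equal(meas, gain_at(f), tolerance = 0.01 * max(gain_at(f), 1e-4))
    # and the analog closed form |H|^2 = 1/(1 + (f/fc)^(2*4)) applied twice
    expect_equal(meas, 1 / (1 + (f / 12)^8), tolerance = 0.05)
  }

  # zero phase: peak cross-correlation between input and output at lag 0
  x <- sin(2 * pi * 3 * t)
  tr <- make_traj(cbind(x, 0 * x, 0 * x), fs = fs)
  y <- lowpass(tr)$xyz[, 1]
  cc <- ccf(y, x, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(lowpass(line_traj(10)), "too short")
})

test_that("spike detection sensitivity and specificity on generator trials", {
  spec <- quick_genspec(seed = 31, spike_rate = 6, tms_amplitude_cm = 0)
  hits <- 0; total <- 0; fp <- 0; clean_n <- 0
  for (i in 1:6) {
    tr <- generate_trial(spec, default_condition(), 1, trial_index = i)
    gt <- attr(tr, "ground_truth")$spikes
    for (ch in names(tr$trajectories)) {
      det <- detect_spikes(tr$trajectories[[ch]])
      truth <- gt[[ch]]
      total <- total + length(truth)
      hits <- hits + sum(truth %in% det)
      n <- n_samples(tr$trajectories[[ch]])
      fp <- fp + length(setdiff(det, truth))
      clean_n <- clean_n + n - length(truth)
    }
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.95)
  expect_lte(fp / clean_n, 0.01)
})

test_that("preprocessing cleans injected artifacts below the movement threshold", {
  spec <- quick_genspec(seed = 13)
  tr <- generate_trial(spec, default_condition(stim_time = "imitation"), 1,
                       trial_index = 3)
  trp <- preprocess_trial(tr)
  rep <- attr(trp, "reports")[["imitator.index"]]
  expect_equal(rep$total_samples, sum(rep$period_lengths))
  # the stretch before the go tone must be still after cleaning
  fs <- 240
  go_i <- round(trp$timeline$imitator_go_tone_s * fs) + 1
  sp <- speed3d(trp$trajectories[["imitator.index"]])
  expect_lt(max(sp[(go_i - 100):(go_i - 10)]), 12)
})
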