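test_that("minimum-jerk closed forms anchor the Beta-profile family", {
  tau <- seq(0, 1, length.out = 101)
  # dbeta(tau, 3, 3) = 30 tau^2 (1 - tau)^2: the two parameterizations agree
  expect_equal(dbeta(tau, 3, 3), minjerk_speed(tau), tolerance = 1e-12)
  # position profile integrates the speed: pbeta is its antiderivative
  expect_equal(minjerk_position(tau), pbeta(tau, 3, 3), tolerance = 1e-12)
  # peak factor solver: identity at factor 1; at 1.15 the skewed profile's
  # peak is 15% higher and earlier (longer deceleration phase)
  expect_equal(imikin:::shape_for_peak_factor(1), c(3, 3))
  s15 <- imikin:::shape_for_peak_factor(1.15)
  expect_equal(imikin:::bell_peak(s15) / dbeta(0.5, 3, 3), 1.15,
               tolerance = 1e-6)
  expect_lt(imikin:::bell_mode(s15), 0.5)
})

test_that("same seed gives bit-identical trials", {
  spec <- quick_genspec(seed = 42)
  t1 <- generate_trial(spec, default_condition(), 2, trial_index = 5)
  t2 <- generate_trial(spec, default_condition(), 2, trial_index = 5)
  for (ch in names(t1$trajectories))
    expect_identical(t1$trajectories[[ch]]$xyz, t2$trajectories[[ch]]$xyz)
  expect_identical(attr(t1, "ground_truth"), attr(t2, "ground_truth"))
  # different trial index differs
  t3 <- generate_trial(spec, default_condition(), 2, trial_index = 6)
  expect_false(identical(t1$trajectories[[1]]$xyz, t3$trajectories[[1]]$xyz))
})

test_that("coupling 1 with no noise gives r = 1; coupling 0.7 calibrates", {
  spec <- quick_genspec(seed = 2, actor_imitator_coupling = 1,
                        noise_sd_cm = 0, spike_rate = 0,
                        tms_amplitude_cm = 0)
  tr <- generate_trial(spec, default_condition(), 1, trial_index = 1)
  ka <- trial_kinematics(tr, "actor")
  ki <- trial_kinematics(tr, "imitator")
  r <- curve_correlation(ka$index$curve, ki$index$curve)
  expect_equal(r, 1, tolerance = 1e-9)

  # Monte-Carlo calibration of the shared-latent attenuation at 0.7:
  # mean r over many independent pairs within +/- 0.03
  n_mov <- round(1.2 * 240) + 1
  eps <- imikin:::coupling_eps(0.7, n_mov, 90, 3, 12)
  set.seed(99)
  rs <- replicate(400, {
    va <- imikin:::simulate_speed_profile(n_mov, 90, 3, eps, 4, 12)
    vb <- imikin:::simulate_speed_profile(n_mov, 90, 3, eps, 4, 12)
    sa <- segment_primary(va); sb <- segment_primary(vb)
    curve_correlation(resample_normalize(va[sa$onset:sa$offset]),
                      resample_normalize(vb[sb$onset:sb$offset]))
  })
  expect_lt(abs(mean(rs) - 0.7), 0.03)
})

test_that("injected effect factor raises digit peak velocity by that factor", {
  # effect cell vs baseline cell, Monte-Carlo over generated movements
  n_mov <- round(1.2 * 240) + 1
  a_eff <- imikin:::shape_for_peak_factor(1.15)
  set.seed(7)
  pv <- function(peak, shape) {
    v <- imikin:::simulate_speed_profile(n_mov, peak, shape, 0.1, 4, 12)
    seg <- segment_primary(v)
    peak_params(v[seg$onset:seg$offset], 240)$PV
  }
  base <- replicate(300, pv(90, 3))
  eff <- replicate(300, pv(90 * 1.15, a_eff))
  expect_equal(mean(eff) / mean(base), 1.15, tolerance = 0.02)
})

test_that("generated experiments have balanced counterbalanced designs", {
  spec <- quick_genspec(seed = 1)
  design <- experiment_design(n_participants = 3,
                              sessions_per_participant = 3,
                              trials_per_session = 8)
  man <- generate_experiment(spec, design)
  expect_equal(nrow(man), 3 * 3 * 8)
  # one site per session, all three sites per participant
  per <- table(man$participant_id, man$site)
  expect_true(all(per == 8))
  # equal meaning split within each session
  split <- table(man$participant_id, man$session, man$meaning)
  expect_true(all(split == 4))
  # reproducible
  man2 <- generate_experiment(spec, design)
  expect_identical(man$site, man2$site)
  expect_identical(attr(man, "trials")[[5]]$trajectories[[1]]$xyz,
                   attr(man2, "trials")[[5]]$trajectories[[1]]$xyz)
})

test_that("opposition generator: exact spacing, count, and touch order", {
  spec <- quick_genspec(seed = 4, noise_sd_cm = 0)
  opp <- generate_opposition(spec, duration_s = 15, iti_ms = 350,
                             iti_jitter_ms = 0)
  d <- diff(opp$touch_times_s)
  expect_true(all(abs(d - 0.35) < 1e-9))
  expect_lte(abs(length(opp$touch_times_s) - floor(15 / 0.35)), 1)
  cyc <- c("index", "middle", "ring", "little", "ring", "middle")
  expect_identical(opp$touch_digits[1:12], rep(cyc, 2))
  expect_equal(length(opp$pulse_times_s), 15)
  expect_error(generate_opposition(spec, iti_ms = 5), "too small")
  expect_error(generate_opposition(spec, duration_s = 10), "epochs")
})
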