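test_that("touch detection recovers generator ground truth", {
  # noiseless geometry: every touch recovered within one sample, none extra
  spec0 <- quick_genspec(seed = 19, noise_sd_cm = 0)
  opp0 <- generate_opposition(spec0, iti_ms = 350, iti_jitter_ms = 20)
  fingers0 <- opp0$trajectories[c("index", "middle", "ring", "little")]
  got0 <- detect_touches(opp0$trajectories$thumb, fingers0)
  expect_equal(nrow(got0), length(opp0$touch_times_s))
  expect_true(all(abs(got0$time_s - opp0$touch_times_s) <= 1 / 240 + 1e-9))

  # sensor noise at the generator default: F1 >= 0.98 with matching at
  # contact scale (50 ms, well under half the inter-touch interval)
  spec <- quick_genspec(seed = 19)
  opp <- generate_opposition(spec, iti_ms = 350, iti_jitter_ms = 20)
  fingers <- opp$trajectories[c("index", "middle", "ring", "little")]
  got <- detect_touches(opp$trajectories$thumb, fingers)
  truth <- opp$touch_times_s
  tol <- 0.05
  matched <- vapply(truth, function(tt) any(abs(got$time_s - tt) <= tol),
                    logical(1))
  spurious <- vapply(got$time_s, function(tt)
    all(abs(truth - tt) > tol), logical(1))
  precision <- 1 - mean(spurious)
  recall <- mean(matched)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.98)
  # recovered order follows the back-and-forth cycle
  cyc <- c("index", "middle", "ring", "little", "ring", "middle")
  expect_identical(got$digit[1:12], rep(cyc, 2))
})

test_that("no contact within range gives an empty result with a warning", {
  far <- list(
    thumb = make_traj(matrix(rep(c(0, 0, 0), each = 100), 100), tracker = "thumb"),
    index = make_traj(matrix(rep(c(10, 0, 0), each = 100), 100)),
    middle = make_traj(matrix(rep(c(12, 0, 0), each = 100), 100), tracker = "middle"),
    ring = make_traj(matrix(rep(c(14, 0, 0), each = 100), 100), tracker = "ring"),
    little = make_traj(matrix(rep(c(16, 0, 0), each = 100), 100), tracker = "little"))
  expect_warning(
    got <- detect_touches(far$thumb, far[c("index", "middle", "ring", "little")]),
    "contact")
  expect_equal(nrow(got), 0)
})

test_that("inter-touch-interval statistics per epoch", {
  # uniform 350 ms touches -> mean 350, sd 0 everywhere
  touches <- data.frame(time_s = seq(0.35, 14.7, by = 0.35))
  out <- iti_stats(touches)
  expect_equal(out$iti_ms, rep(350, 3), tolerance = 1e-9)
  expect_equal(out$iti_sd_ms, rep(0, 3), tolerance = 1e-9)
  # interval count conservation over the full recording
  expect_equal(sum(out$n_intervals), nrow(touches) - 1)

  # alternating 300/400 ms: mean 350, sd by the n-1 formula
  times <- cumsum(c(0.5, rep(c(0.3, 0.4), 5)))
  out2 <- iti_stats(data.frame(time_s = times))
  pre <- out2[out2$epoch == "pre", ]
  iv_pre <- diff(times)[times[-1] < 5] * 1000  # hand-assigned oracle
  expect_equal(pre$iti_ms, mean(iv_pre))
  expect_equal(pre$iti_sd_ms, sd(iv_pre))

  # single touch in an epoch -> missing values
  lone <- data.frame(time_s = c(2.0, 12.0))
  out3 <- iti_stats(lone)
  expect_true(is.na(out3$iti_ms[out3$epoch == "pre"]))
  expect_true(is.na(out3$iti_sd_ms[out3$epoch == "post"]))
})

test_that("epoch speeds: half-open epochs, finger averaging, known scalings", {
  # stationary hand -> zero in all epochs
  n <- 15 * 240 + 1
  still <- lapply(c("thumb", "index", "middle", "ring", "little"),
                  function(tr) make_traj(matrix(1, n, 3), tracker = tr))
  names(still) <- c("thumb", "index", "middle", "ring", "little")
  out <- epoch_speeds(still)
  expect_equal(out$finger_speed_cm_s, rep(0, 3))
  expect_equal(out$thumb_speed_cm_s, rep(0, 3))

  # speed doubled in the stim epoch
  fs <- 240; t <- (seq_len(n) - 1) / fs
  vx <- ifelse(t >= 5 & t < 10, 2, 1)
  x <- cumsum(vx) / fs
  mov <- lapply(names(still), function(tr)
    make_traj(cbind(x, 0 * x, 0 * x), tracker = tr))
  names(mov) <- names(still)
  out2 <- epoch_speeds(mov)
  expect_equal(out2$finger_speed_cm_s[2] / out2$finger_speed_cm_s[1], 2,
               tolerance = 0.01)
})

test_that("opposition_result assembles the full per-recording measure set", {
  spec <- quick_genspec(seed = 37)
  opp <- generate_opposition(spec, iti_ms = 350, iti_jitter_ms = 10)
  res <- opposition_result(opp$trajectories)
  expect_s3_class(res, "imk_opposition_result")
  expect_equal(sum(res$iti$n_intervals), nrow(res$touches) - 1)
  expect_true(all(res$iti$iti_ms > 250 & res$iti$iti_ms < 450, na.rm = TRUE))
  expect_true(all(res$speeds$thumb_speed_cm_s > 0))
})
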