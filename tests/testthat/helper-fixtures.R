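# Small trajectory fixtures built in code.

make_traj <- function(xyz, fs = 240, tracker = "index", person = "imitator",
                      angles = NULL) {
  trajectory(tracker, person, fs, xyz, angles)
}

# straight-line path at constant velocity (cm/s per axis)
line_traj <- function(n = 100, v = c(10, 0, 0), fs = 240, x0 = c(0, 0, 0)) {
  t <- (seq_len(n) - 1) / fs
  make_traj(cbind(x0[1] + v[1] * t, x0[2] + v[2] * t, x0[3] + v[3] * t),
            fs = fs)
}

# minimum-jerk movement of amplitude D (cm) over T_s seconds along +x
minjerk_traj <- function(D = 30, T_s = 1, fs = 240, pad = 0) {
  n <- round(T_s * fs) + 1
  tau <- seq(0, 1, length.out = n)
  x <- D * minjerk_position(tau)
  x <- c(rep(0, pad), x, rep(D, pad))
  make_traj(cbind(x, 0 * x, 0 * x), fs = fs)
}

default_condition <- function(site = "PMv", stim_time = "imitation") {
  list(site = site, stim_time = stim_time, meaning = "meaningful",
       effector = "finger")
}

quick_genspec <- function(seed = 1, ...) generator_spec(seed = seed, ...)
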