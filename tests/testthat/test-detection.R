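make_stream_from_theta <- function(theta, ...) {
  render_stream(theta, noise_sd_deg = 0, pupil_noise_au = 0, ...)
}

test_that("Savitzky-Golay velocity is exact for polynomial motion", {
  t <- (0:999) / 1000
  # constant position
  st <- make_stream_from_theta(matrix(1.5, 1000, 2))
  vel <- sg_velocity(st)
  expect_lt(max(abs(vel$v)), 1e-9)
  # linear ramp: k deg/ms on x -> 1000 k deg/s on interior samples
  k <- 0.004
  st <- make_stream_from_theta(cbind(k * 1000 * t, 0))
  vel <- sg_velocity(st)
  expect_equal(vel$vx[4:997], rep(1000 * k, 994), tolerance = 1e-9)
  # cubic position: derivative exact vs the analytic polynomial
  thx <- 0.5 + 3 * t - 4 * t^2 + 2 * t^3
  thy <- -0.2 + 1.5 * t + t^2 - 0.5 * t^3
  st <- make_stream_from_theta(cbind(thx, thy))
  vel <- sg_velocity(st)
  expect_equal(vel$vx[4:997], (3 - 8 * t + 6 * t^2)[4:997], tolerance = 1e-9)
  expect_equal(vel$vy[4:997], (1.5 + 2 * t - 1.5 * t^2)[4:997],
               tolerance = 1e-9)
  expect_error(sg_velocity(st[1:5, ]), "window")
})

test_that("SG velocity commutes with offsets and scales with the signal", {
  set.seed(8)
  theta <- cbind(cumsum(rnorm(500, 0, 0.01)), cumsum(rnorm(500, 0, 0.01)))
  v1 <- sg_velocity(make_stream_from_theta(theta))
  v2 <- sg_velocity(make_stream_from_theta(sweep(theta, 2, c(2, -1), `+`)))
  expect_equal(v1$vx, v2$vx, tolerance = 1e-6)
  expect_equal(v1$vy, v2$vy, tolerance = 1e-6)
  v3 <- sg_velocity(make_stream_from_theta(3 * theta))
  expect_equal(v3$vx, 3 * v1$vx, tolerance = 1e-6)
})

test_that("noise estimator recovers a pure Gaussian velocity noise level", {
  set.seed(31)
  for (s in c(5, 12)) {
    vel <- fake_velocity(rnorm(10000, 0, s))
    vel$vy <- vel$vx
    ns <- estimate_noise_sigma(vel)
    expect_equal(ns$sigma_x, s, tolerance = 0.10)
    expect_equal(ns$eta_x, 3 * ns$sigma_x)
    expect_equal(ns$eta, 3 * max(ns$sigma_x, ns$sigma_y))
  }
})

test_that("noise estimator is robust to sparse saccadic peaks and zero signals", {
  set.seed(32)
  base <- rnorm(10000, 0, 10)
  vel0 <- fake_velocity(base)
  s0 <- estimate_noise_sigma(vel0)$sigma_x
  spiked <- base
  for (at in seq(500, 9500, by = 1000)) spiked[at:(at + 30)] <- 300
  s1 <- estimate_noise_sigma(fake_velocity(spiked))$sigma_x
  expect_lt(abs(s1 - s0) / s0, 0.05)
  # all-zero signal: floored sigma, no crash
  nz <- estimate_noise_sigma(fake_velocity(rep(0, 100)))
  expect_equal(nz$sigma_x, 1e-6)
  expect_gt(nz$eta, 0)
})

test_that("saccade detection equals the brute-force run scan on random signals", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(30:150, 1)
    v <- abs(rnorm(n, 0, 20))
    nb <- sample(0:3, 1)
    for (b in seq_len(nb)) {
      at <- sample(n - 10, 1)
      v[at:(at + sample(2:9, 1))] <- runif(1, 80, 300)
    }
    eta <- 50
    ev <- detect_saccades(fake_velocity(v), eta, min_run = 6)
    oracle <- brute_force_runs(v, eta, 6)
    expect_equal(nrow(ev), nrow(oracle))
    if (nrow(ev) > 0) {
      expect_equal(ev$onset_idx, oracle[, 1])
      expect_equal(ev$offset_idx, oracle[, 2])
    }
  }
})

test_that("runs shorter than six samples are never events", {
  v <- rep(0, 100)
  v[40:44] <- 200                       # five supra-threshold samples
  expect_equal(nrow(detect_saccades(fake_velocity(v), 50)), 0)
  v[40:45] <- 200                       # six samples
  ev <- detect_saccades(fake_velocity(v), 50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_idx, 40)
  expect_equal(ev$offset_idx, 45)
  # constant fixation: empty list
  expect_equal(nrow(detect_saccades(fake_velocity(rep(0, 50)), 50)), 0)
})

test_that("saccade metrics report amplitude, peak velocity and direction", {
  # noiseless 10-degree horizontal saccade
  tg <- gaze_to_screen_px(rbind(c(-5, 0), c(5, 0)))
  st <- simulate_trial(tg, noise_sd_deg = 0, pupil_noise_au = 0,
                       motion_seed = 41)
  ev <- detect_events(st)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_deg, 10, tolerance = 0.23 / 10)
  vel <- attr(ev, "velocity")
  expect_equal(ev$peak_velocity_dps,
               max(vel$v[ev$onset_idx:ev$offset_idx]))
  expect_equal(ev$peak_velocity_dps, 300, tolerance = 9 / 300)
  # pure upward move: direction 90 degrees in screen-up convention
  # (lattice-aligned 4.5-degree targets and a zero positioning error keep
  # the executed move exactly vertical)
  tg_up <- gaze_to_screen_px(rbind(c(0, 4.5), c(0, -4.5)))
  st_up <- simulate_trial(tg_up, motor = motor_config(quant_error_microsteps = 0),
                          noise_sd_deg = 0, pupil_noise_au = 0,
                          motion_seed = 42)
  ev_up <- detect_events(st_up)
  expect_equal(ev_up$direction_deg, 90, tolerance = 1e-6)
})

test_that("event count matches the planned moves on simulated grids", {
  for (noise in c(0.02, 0.05)) {
    hits <- 0
    total <- 0
    for (tr in 1:3) {
      st <- simulate_trial(calibration_grid(), noise_sd_deg = noise,
                           motion_seed = 50 + tr, noise_seed = 60 + tr)
      ev <- detect_events(st)
      truth <- attr(st, "truth")
      hits <- hits + length(intersect(truth$move, ev$move))
      total <- total + nrow(truth)
      if (noise == 0.02) expect_equal(nrow(ev), nrow(truth))
    }
    expect_equal(hits, total)  # recall 1.0
  }
})

test_that("detected saccades have single-peaked velocity profiles on clean input", {
  tg <- gaze_to_screen_px(cbind(seq(-12, 12, by = 6), 0))
  st <- simulate_trial(tg, noise_sd_deg = 0, pupil_noise_au = 0,
                       motion_seed = 43)
  ev <- detect_events(st)
  vel <- attr(ev, "velocity")
  expect_equal(nrow(ev), nrow(tg) - 1)
  for (i in seq_len(nrow(ev))) {
    v <- vel$v[ev$onset_idx[i]:ev$offset_idx[i]]
    pk <- which.max(v)
    expect_true(all(diff(v[1:pk]) > -0.5))
    expect_true(all(diff(v[pk:length(v)]) < 0.5))
  }
})

test_that("fixation windows avoid events and recover commanded positions", {
  st <- simulate_trial(calibration_grid(), noise_sd_deg = 0,
                       pupil_noise_au = 0, motion_seed = 44)
  ev <- detect_events(st)
  fx <- extract_fixations(st, ev)
  expect_equal(nrow(fx), 13)
  expect_setequal(fx$target_index, 1:13)
  # means within the positioning-error bound of the planned targets
  dev_deg <- px_to_deg(sqrt((fx$mean_x - fx$planned_x)^2 +
                              (fx$mean_y - fx$planned_y)^2))
  expect_lte(max(dev_deg), 2 * 0.1125 * sqrt(2) + 0.01)
  # windows are the guarded complement of the events: every window lies
  # strictly between the surrounding events' offset and onset
  starts <- c(1L, ev$offset_idx + 1L) + 20L
  ends <- c(ev$onset_idx - 1L, nrow(st)) - 20L
  expect_true(all(starts <= ends))
  in_event <- rep(FALSE, nrow(st))
  for (i in seq_len(nrow(ev)))
    in_event[ev$onset_idx[i]:ev$offset_idx[i]] <- TRUE
  for (i in seq_along(starts))
    expect_false(any(in_event[starts[i]:ends[i]]))
})
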