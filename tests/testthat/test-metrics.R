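fake_fixations <- function(means_x, means_y, target_index, n = 260,
                           ss_x = 0, ss_y = 0, pupil = 2800) {
  data.frame(target_index = target_index, n = n, mean_x = means_x,
             mean_y = means_y, sd_x = sqrt(ss_x / (n - 1)),
             sd_y = sqrt(ss_y / (n - 1)), ss_x = ss_x, ss_y = ss_y,
             mean_pupil = pupil)
}

test_that("accuracy table reports signed deviations per coordinate", {
  g <- calibration_grid()
  fx <- rbind(fake_fixations(969.7, 532.4, 1), fake_fixations(969.7, 532.4, 1))
  acc <- accuracy_table(fx, g)
  expect_equal(nrow(acc), 13)
  expect_equal(acc$dev_x_px[1], 9.7)
  expect_equal(acc$dev_y_px[1], -7.6)
  expect_equal(acc$dev_x_deg[1], px_to_deg(9.7))
  expect_true(all(acc$absent[-1]))
  expect_true(is.na(acc$mean_x[2]))
})

test_that("a constant pixel bias shifts every accuracy deviation exactly", {
  g <- calibration_grid()
  run_one <- function(bias) {
    fx_all <- lapply(1:2, function(tr) {
      st <- simulate_trial(g, motion_seed = 70 + tr, noise_seed = 80 + tr,
                           bias_px = bias)
      fx <- extract_fixations(st, detect_events(st))
      fx$trial <- tr
      fx
    })
    accuracy_table(do.call(rbind, fx_all), g)
  }
  a0 <- run_one(c(0, 0))
  a5 <- run_one(c(5, 0))
  expect_equal(a5$dev_x_px, a0$dev_x_px + 5, tolerance = 1e-9)
  expect_equal(a5$dev_y_px, a0$dev_y_px, tolerance = 1e-9)
})

test_that("precision table pools within-trial dispersion and needs >= 2 trials", {
  g <- calibration_grid()
  set.seed(90)
  # two trials per coordinate with known raw dispersion
  fx <- do.call(rbind, lapply(1:2, function(tr) {
    f <- fake_fixations(unclass(g)[, 1], unclass(g)[, 2], 1:13, n = 101,
                        ss_x = 100 * 1.2^2, ss_y = 100 * 0.8^2)
    f$trial <- tr
    f
  }))
  prec <- precision_table(fx, g)
  expect_equal(prec$sd_x_px, rep(1.2, 13), tolerance = 1e-12)
  expect_equal(prec$sd_y_px, rep(0.8, 13), tolerance = 1e-12)
  expect_equal(prec$sd_x_deg, px_to_deg(prec$sd_x_px))
  expect_error(precision_table(fx[fx$trial == 1, ], g), ">= 2 trials")
  # noiseless simulation: static fixations have (near) zero dispersion
  fx0 <- do.call(rbind, lapply(1:2, function(tr) {
    st <- simulate_trial(g, noise_sd_deg = 0, pupil_noise_au = 0,
                         motion_seed = 91 + tr)
    f <- extract_fixations(st, detect_events(st))
    f$trial <- tr
    f
  }))
  p0 <- precision_table(fx0, g)
  expect_lt(max(p0$sd_x_px, p0$sd_y_px), 0.01)
})

test_that("exclusion filter drops transitions, fragments and out-of-range amplitudes", {
  ev <- data.frame(amplitude_deg = c(8, 3, 16, 10, 5, 7),
                   is_transition = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                   is_fragment = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  fl <- exclusion_filter(ev)
  expect_equal(fl$log$count[fl$log$reason == "transition"], 1)
  expect_equal(fl$log$count[fl$log$reason == "fragment"], 1)
  expect_equal(fl$log$count[fl$log$reason == "amplitude"], 2)
  expect_equal(fl$log$count[fl$log$reason == "retained"], 2)
  expect_equal(fl$events$amplitude_deg, c(5, 7))
  # boundary amplitudes 4.0 and 14.6 are retained
  fl2 <- exclusion_filter(data.frame(amplitude_deg = c(4.0, 14.6, 3.99)))
  expect_equal(fl2$log$count[fl2$log$reason == "retained"], 2)
})

test_that("main sequence fit is exact OLS with the v10 identity", {
  A <- c(4.5, 6, 8, 10.5, 12, 14)
  sac <- data.frame(amplitude_deg = A, peak_velocity_dps = 20 * A + 100)
  fit <- main_sequence_fit(sac)
  expect_equal(unname(coef(fit)), c(100, 20), tolerance = 1e-12)
  expect_equal(fit$v10, 300, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$v10,
               unname(coef(fit)["intercept"] + 10 * coef(fit)["slope"]))
  expect_equal(unname(predict(fit, 12)), 340, tolerance = 1e-12)
  # OLS equals the normal-equation solution on random data
  set.seed(101)
  for (rep in 1:20) {
    x <- runif(30, 4, 15)
    y <- 250 + 12 * x + rnorm(30, 0, 20)
    f <- main_sequence_fit(data.frame(amplitude_deg = x,
                                      peak_velocity_dps = y))
    expect_equal(unname(coef(f)), ols_normal_eq(x, y), tolerance = 1e-9)
  }
  expect_error(main_sequence_fit(sac[1:2, ]), "at least 3")
  expect_error(main_sequence_fit(
    data.frame(amplitude_deg = rep(8, 5), peak_velocity_dps = rnorm(5))),
    "degenerate")
})

test_that("R-squared is invariant to affine rescaling of amplitude", {
  set.seed(102)
  x <- runif(40, 4, 15)
  y <- 250 + 12 * x + rnorm(40, 0, 25)
  f1 <- main_sequence_fit(data.frame(amplitude_deg = x,
                                     peak_velocity_dps = y))
  f2 <- main_sequence_fit(data.frame(amplitude_deg = 60 * x + 7,
                                     peak_velocity_dps = y))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("clean experiments retain everything except transitions and band-edge saccades", {
  ex <- simulate_experiment(5, 30, seed = 61)
  for (p in seq_along(ex)) {
    for (s in ex[[p]]$streams) {
      ev <- detect_events(s)
      fl <- exclusion_filter(ev)
      lg <- setNames(fl$log$count, fl$log$reason)
      expect_equal(unname(lg["fragment"]), 0)
      expect_equal(unname(lg["transition"]), sum(ev$is_transition))
      expect_false(any(fl$events$is_transition))
      # amplitude drops can only be planned-edge saccades nudged across
      # the band by positioning error (<= 0.318 deg) plus threshold
      # clipping and endpoint noise
      dropped <- ev$amplitude_deg[!ev$is_transition &
                                    (ev$amplitude_deg < 4 |
                                       ev$amplitude_deg > 14.6)]
      if (length(dropped) > 0)
        expect_true(all(pmin(abs(dropped - 4), abs(dropped - 14.6)) < 0.7))
      expect_gte(lg["retained"] / (lg["total"] - lg["transition"]), 0.98)
    }
  }
})

test_that("per-condition v10 is identical for identical streams and drops sparse cells", {
  # null model with shared noise: conditions are byte-identical
  ex <- simulate_experiment(2, 6, seed = 31,
                            condition_independent_noise = TRUE)
  evs <- do.call(rbind, lapply(ex, function(p)
    do.call(rbind, lapply(p$streams, function(s)
      exclusion_filter(detect_events(s))$events))))
  res <- per_condition_v10(evs, c("dark", "medium", "light"))
  expect_equal(res$v10[, "dark"], res$v10[, "light"], tolerance = 1e-12)
  expect_equal(unname(res$grand["dark"]), unname(res$grand["medium"]),
               tolerance = 1e-12)
  # a participant with too few saccades in one condition is excluded
  ev2 <- data.frame(participant = rep(c(1, 1, 1, 1, 2), 3),
                    condition = rep(c("dark", "medium", "light"), each = 5),
                    amplitude_deg = c(5, 7, 9, 11, 6),
                    peak_velocity_dps = c(210, 250, 290, 320, 230))
  ev2 <- ev2[!(ev2$participant == 2 & ev2$condition == "light"), ]
  expect_warning(res2 <- per_condition_v10(ev2, c("dark", "medium", "light")),
                 "excluded")
  expect_equal(rownames(res2$v10), "1")
  expect_equal(res2$excluded, 2)
})
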