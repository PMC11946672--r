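test_that("pixel/mm/degree conversion chain reproduces the printed accuracy table pairs", {
  scr <- screen_geometry()
  expect_equal(px_to_mm(1920, scr), 531.36)
  expect_equal(px_to_mm(0, scr), 0)
  expect_equal(px_to_mm(38.5, scr), 10.65, tolerance = 0.02 / 10.65)
  expect_equal(mm_to_deg(0, 700), 0)
  expect_equal(round(mm_to_deg(3.5, 700), 2), 0.29)
  expect_equal(round(mm_to_deg(10.65, 927), 2), 0.66)
  expect_equal(round(px_to_deg(9.7, scr), 2), 0.17)
  expect_equal(round(px_to_deg(0.28, scr), 3), 0.005)
  expect_equal(px_to_deg(0, scr), 0)

  # the full printed deviation rows: px cell -> mm and degree cells
  dev_x_px <- c(9.7, 19.1, 16.6, 5.5, -2.9, 19.5, 9.0, 15.2, 38.5,
                -8.2, -5.3, -13.3, -3.2)
  dev_x_mm <- c(2.69, 5.28, 4.60, 1.53, -0.81, 5.41, 2.50, 4.21, 10.67,
                -2.27, -1.46, -3.67, -0.88)
  dev_x_deg <- c(0.17, 0.33, 0.28, 0.09, -0.05, 0.33, 0.15, 0.26, 0.66,
                 -0.14, -0.09, -0.23, -0.05)
  dev_y_px <- c(-7.60, 10.09, 3.20, 6.85, -2.34, -2.06, -12.5, -5.59,
                17.43, -18.5, -9.18, -10.2, -8.91)
  dev_y_mm <- c(-2.10, 2.79, 0.89, 1.90, -0.65, -0.57, -3.45, -1.55,
                4.82, -5.12, -2.54, -2.83, -2.47)
  dev_y_deg <- c(-0.13, 0.17, 0.05, 0.12, -0.04, -0.04, -0.21, -0.10,
                 0.30, -0.32, -0.16, -0.17, -0.15)
  # printed precision rows (the first Y px cell, 0.06, is inconsistent
  # with its own mm/degree cells - 1.06 px would match - and is skipped)
  sd_x_px <- c(0.89, 0.88, 0.38, 0.78, 2.24, 0.91, 0.97, 1.26, 0.60,
               2.06, 0.28, 0.70, 0.62)
  sd_x_mm <- c(0.25, 0.24, 0.11, 0.22, 0.62, 0.25, 0.27, 0.35, 0.17,
               0.57, 0.08, 0.19, 0.17)
  sd_x_deg <- c(0.02, 0.02, 0.01, 0.01, 0.04, 0.02, 0.02, 0.02, 0.01,
                0.04, 0.00, 0.01, 0.01)
  sd_y_px <- c(0.75, 1.12, 0.96, 1.76, 0.88, 0.97, 1.58, 2.34, 2.55,
               1.03, 0.75, 0.77)
  sd_y_mm <- c(0.21, 0.31, 0.27, 0.49, 0.24, 0.27, 0.44, 0.65, 0.71,
               0.29, 0.21, 0.21)
  sd_y_deg <- c(0.01, 0.02, 0.02, 0.03, 0.02, 0.02, 0.03, 0.04, 0.04,
                0.02, 0.01, 0.01)
  px <- c(dev_x_px, dev_y_px, sd_x_px, sd_y_px)
  mm <- c(dev_x_mm, dev_y_mm, sd_x_mm, sd_y_mm)
  deg <- c(dev_x_deg, dev_y_deg, sd_x_deg, sd_y_deg)
  # +-1 unit in the last printed digit of the pre-rounded px entries
  expect_true(all(abs(px_to_mm(px, scr) - mm) <= 0.02))
  expect_true(all(abs(px_to_deg(px, scr) - deg) <= 0.015))
})

test_that("Weber contrast reproduces the three condition values and rejects bad input", {
  expect_equal(round(weber_contrast(2.74, 0.89), 2), 0.68)
  expect_equal(round(weber_contrast(47.09, 6.83), 2), 0.85)
  expect_equal(round(weber_contrast(232.03, 40.24), 2), 0.83)
  expect_equal(weber_contrast(55, 55), 0)
  expect_error(weber_contrast(0, 1), "positive")
  bc <- brightness_conditions()
  expect_equal(round(bc$C_W, 2), c(0.68, 0.85, 0.83))
  expect_true(all(bc$C_W >= 0 & bc$C_W <= 1))
})

test_that("stepper arithmetic: resolution, speed and positioning error", {
  expect_identical(microstep_resolution(1.8, 16), 0.1125)
  expect_identical(microstep_resolution(1.8, 1), 1.8)
  expect_identical(microstep_resolution(0.9, 16), 0.05625)
  expect_error(microstep_resolution(1.8, 0))
  expect_equal(pps_to_dps(3200, 0.1125), 360)
  expect_equal(pps_to_dps(0, 0.1125), 0)
  expect_equal(pps_to_dps(5000, 0.1125), 562.5)
  expect_equal(positioning_error(2, 0.1125), 0.225)
  expect_equal(positioning_error(0, 0.1125), 0)
  expect_equal(positioning_error(16, 0.1125), 1.8)
  expect_error(positioning_error(-1))
})

test_that("laser displacement follows the doubled-tangent convention", {
  rig <- laser_rig()
  d135 <- laser_displacement(15 * 0.9, rig)
  expect_equal(signif(d135 / 10, 3), 33.6)           # cm, 3 s.f.
  expect_lt(d135, rig$canvas_width_mm / 2)           # stays on canvas
  expect_equal(laser_displacement(0, rig), 0)
  expect_equal(laser_displacement(0.9, rig), 22.0, tolerance = 0.1 / 22)
  expect_equal(laser_displacement(-13.5, rig), -d135)
  # exact specular reflection is the alternate model and differs by ~2 cm
  expect_equal(laser_displacement(13.5, rig, model = "specular"),
               700 * tan(27 * pi / 180))
  expect_error(laser_displacement(46, rig), "range")
})

test_that("apparent pupil area is a cosine of the gaze-to-camera angle", {
  cam_axis <- camera_geometry(c(0, 0, 530))
  base <- 1000
  expect_equal(apparent_pupil_area(c(0, 0, 1), cam_axis, base), base)
  g60 <- c(sin(pi / 3), 0, cos(pi / 3))
  expect_equal(apparent_pupil_area(g60, cam_axis, base), base / 2)
  expect_equal(apparent_pupil_area(c(1, 0, 0), cam_axis, base), 0)
  expect_equal(apparent_pupil_area(c(0.5, 0, -0.8), cam_axis, base), 0)
  # strictly decreasing in the angle
  gam <- seq(0, 85, by = 5) * pi / 180
  areas <- apparent_pupil_area(cbind(sin(gam), 0, cos(gam)), cam_axis, base)
  expect_true(all(diff(areas) < 0))
  expect_error(apparent_pupil_area(c(0, 0, 1), cam_axis, -1))
})

test_that("pupil area is invariant under rotation about the eye-camera axis", {
  cam <- camera_geometry()
  g0 <- c(sin(0.2), 0.1, cos(0.2))
  g0 <- g0 / sqrt(sum(g0^2))
  a0 <- apparent_pupil_area(g0, cam)
  for (ang in c(0.3, 1.1, 2.5, 4.9)) {
    g <- rotate_about(g0, cam$unit, ang)
    expect_equal(apparent_pupil_area(g, cam), a0, tolerance = 1e-9)
  }
})

test_that("default camera placement orders pupil area left-down > right-up", {
  cam <- camera_geometry()
  ecc <- tan(10 * pi / 180)
  left_down <- c(-ecc, ecc, 1)
  right_up <- c(ecc, -ecc, 1)
  expect_gt(apparent_pupil_area(left_down / sqrt(sum(left_down^2)), cam),
            apparent_pupil_area(right_up / sqrt(sum(right_up^2)), cam))
})

test_that("target-to-gaze-angle mapping is centred, correct and invertible", {
  scr <- screen_geometry()
  expect_equal(as.vector(target_to_gaze_angles(c(960, 540), scr)), c(0, 0))
  # atan(845 px * 0.27675 mm/px / 927 mm)
  th <- target_to_gaze_angles(c(1805, 540), scr)
  expect_equal(unname(th[1, 1]),
               atan(845 * (531.36 / 1920) / 927) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(unname(th[1, 1]), 14.16, tolerance = 0.05 / 14.16)
  set.seed(1)
  pts <- cbind(runif(25, 0, 1920), runif(25, 0, 1080))
  back <- gaze_to_screen_px(target_to_gaze_angles(pts, scr), scr)
  expect_equal(unname(back), unname(pts), tolerance = 1e-9)
  expect_warning(target_to_gaze_angles(c(2000, 540), scr), "outside")
})

test_that("screen geometry validates its fields and has square pixels", {
  scr <- screen_geometry()
  expect_equal(scr$width_mm / scr$width_px, scr$height_mm / scr$height_px,
               tolerance = 1e-4)
  expect_error(screen_geometry(width_mm = -1), "positive")
  expect_warning(screen_geometry(width_mm = 600), "non-square")
  expect_error(camera_geometry(c(0, 0, -10)), "front")
  expect_error(laser_rig(canvas_distance_mm = 0), "positive")
})
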