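# Deterministic sub-seed derivation (kept below 2^31 - 1).
child_seed <- function(seed, ...) {
  s <- as.double(as.integer(seed) %% 2147483647L)
  for (i in c(...)) s <- (s * 48271 + i + 1) %% 2147483647
  as.integer(s)
}

# Build the noiseless gimbal gaze-angle trajectory for an ordered target
# sequence: fixations of fixation_ms between trapezoidal moves, each axis
# snapped to the microstep lattice plus a seeded +-quant_error_microsteps
# positioning error per move. Returns the 1 kHz theta matrix and a ground
# truth table of move intervals (sample indices are 0-based ms).
build_motion <- function(targets_px, screen = screen_geometry(),
                         motor = motor_config(), fixation_ms = 300,
                         seed = 1, home_px = NULL) {
  th_plan <- target_to_gaze_angles(unclass(targets_px), screen)
  n_tg <- nrow(th_plan)
  res <- motor$resolution_deg
  q <- motor$quant_error_microsteps
  set.seed(child_seed(seed, 7L))
  # executed target: a microstep-lattice point within +-q microsteps of
  # the commanded angle (the drive chain's positioning-error bound)
  snap <- function(th) {
    vapply(th, function(a) {
      base <- round(a / res)
      if (q == 0) return(base * res)
      cand <- base + (-q):q
      cand <- cand[abs(cand * res - a) <= q * res]
      sample(cand, 1) * res
    }, numeric(1))
  }
  has_transition <- !is.null(home_px)
  if (has_transition) {
    th_seq <- rbind(target_to_gaze_angles(home_px, screen), th_plan)
  } else {
    th_seq <- th_plan
  }
  exec <- t(apply(th_seq, 1, snap))
  if (has_transition) exec[1, ] <- th_seq[1, ]  # home is wherever the eye is

  pieces <- list(matrix(rep(exec[1, ], each = fixation_ms), ncol = 2))
  truth <- vector("list", nrow(exec) - 1)
  t_cur <- fixation_ms
  for (i in seq_len(nrow(exec) - 1)) {
    mv <- superpose_axes(
      motor_move_profile(exec[i + 1, 1] - exec[i, 1], motor),
      motor_move_profile(exec[i + 1, 2] - exec[i, 2], motor))
    mv <- sweep(mv, 2, exec[i, ], `+`)
    fix <- matrix(rep(exec[i + 1, ], each = fixation_ms), ncol = 2)
    pieces[[length(pieces) + 1]] <- mv
    pieces[[length(pieces) + 1]] <- fix
    truth[[i]] <- data.frame(
      move = i,
      onset_ms = t_cur,
      offset_ms = t_cur + nrow(mv) - 1,
      amp_exec_deg = sqrt(sum((exec[i + 1, ] - exec[i, ])^2)),
      is_transition = has_transition && i == 1L)
    t_cur <- t_cur + nrow(mv) + fixation_ms
  }
  theta <- do.call(rbind, pieces)
  colnames(theta) <- c("theta_x", "theta_y")
  list(theta = theta, truth = do.call(rbind, truth),
       targets_px = unclass(targets_px), exec_deg = exec,
       has_transition = has_transition, fixation_ms = fixation_ms)
}

#' Render a gimbal trajectory into a tracker sample stream
#'
#' Forward model from gimbal gaze angles to what the video tracker reports
#' at 1000 Hz: angles are mapped to screen pixels (the inverse of
#' [target_to_gaze_angles()]), i.i.d. Gaussian position noise of
#' `noise_sd_deg` (converted to pixels) is added per axis, and the pupil
#' channel is the foreshortened apparent area from [apparent_pupil_area()]
#' for the true gaze direction plus optional Gaussian pupil noise.
#' Fully reproducible from the seed.
#'
#' @param motion a motion object from the trial simulator, or a plain
#'   n x 2 matrix of gaze angles in degrees
#' @param screen a [screen_geometry()]
#' @param camera a [camera_geometry()]
#' @param noise_sd_deg SD of the position noise, degrees (>= 0);
#'   the default 0.02 deg matches the sub-pixel-to-few-pixel sample SDs
#'   a well-focused video tracker shows on a static target
#' @param pupil_base_au true pupil area in tracker units (2888.94 a.u.
#'   corresponds to the 5 mm artificial pupil)
#' @param pupil_noise_au SD of pupil measurement noise, a.u.
#' @param bias_px constant `(x, y)` pixel offset added to every sample
#'   (models a calibration offset; default none)
#' @param seed integer RNG seed
#' @return a `data.frame` of class `sample_stream` with columns `t_ms`,
#'   `x_px`, `y_px`, `pupil_au` and the simulation metadata in attributes
#'   (`truth`, `targets_px`, `screen`, `camera`, `fs_hz`, seeds)
#' @export
render_stream <- function(motion, screen = screen_geometry(),
                          camera = camera_geometry(),
                          noise_sd_deg = 0.02, pupil_base_au = 2888.94,
                          pupil_noise_au = 2, bias_px = c(0, 0), seed = 1) {
  stopifnot(noise_sd_deg >= 0)
  if (is.matrix(motion)) motion <- list(theta = motion, truth = NULL,
                                        targets_px = NULL,
                                        has_transition = FALSE,
                                        fixation_ms = NA)
  theta <- motion$theta
  n <- nrow(theta)
  px <- gaze_to_screen_px(theta, screen)
  sd_px <- tan(noise_sd_deg * pi / 180) * screen$viewing_distance_mm /
    screen$pitch_mm
  set.seed(child_seed(seed, 11L))
  if (sd_px > 0) px <- px + matrix(stats::rnorm(2 * n, 0, sd_px), ncol = 2)
  px <- sweep(px, 2, bias_px, `+`)
  gv <- cbind(tan(theta[, 1] * pi / 180), tan(theta[, 2] * pi / 180), 1)
  pupil <- apparent_pupil_area(gv / sqrt(rowSums(gv^2)), camera,
                               pupil_base_au)
  if (pupil_noise_au > 0) pupil <- pupil + stats::rnorm(n, 0, pupil_noise_au)
  out <- data.frame(t_ms = 0:(n - 1), x_px = px[, 1], y_px = px[, 2],
                    pupil_au = pmax(pupil, .Machine$double.eps))
  structure(out, class = c("sample_stream", "data.frame"),
            fs_hz = 1000, truth = motion$truth,
            targets_px = motion$targets_px,
            has_transition = isTRUE(motion$has_transition),
            fixation_ms = motion$fixation_ms,
            screen = screen, camera = camera,
            noise_sd_deg = noise_sd_deg, pupil_base_au = pupil_base_au,
            pupil_noise_au = pupil_noise_au, seed = as.integer(seed))
}

#' Simulate one trial of a target pattern
#'
#' Runs the gimbal through an ordered target sequence (300 ms fixation per
#' target between trapezoidal moves, microstep quantization and the
#' +-2-microstep positioning error included) and renders the tracker
#' sample stream. `motion_seed` controls the motor positioning errors,
#' `noise_seed` the measurement noise, so the same physical motion can be
#' re-recorded under independent noise (e.g. one per brightness condition).
#'
#' @param targets a pattern matrix of `(x_px, y_px)` targets, e.g.
#'   [calibration_grid()] or [plan_random_saccades()]
#' @param screen,camera,motor geometry and motor configuration objects
#' @param fixation_ms fixation duration per target, ms
#' @param home_px optional `(x, y)` start position; when given, the first
#'   move (home to first target) is flagged as a transition in the ground
#'   truth, as between-participant repositioning moves are
#' @param motion_seed,noise_seed integer seeds
#' @param ... passed to [render_stream()] (noise and pupil parameters)
#' @return a `sample_stream`
#' @export
simulate_trial <- function(targets, screen = screen_geometry(),
                           camera = camera_geometry(),
                           motor = motor_config(), fixation_ms = 300,
                           home_px = NULL, motion_seed = 1,
                           noise_seed = motion_seed, ...) {
  motion <- build_motion(targets, screen, motor, fixation_ms,
                         seed = motion_seed, home_px = home_px)
  render_stream(motion, screen, camera, seed = noise_seed, ...)
}

#' Simulate the full brightness experiment dataset
#'
#' Generates the null-model dataset: each artificial participant gets one
#' random saccade plan ([plan_random_saccades()]) that is reused across
#' all brightness conditions, so the condition affects metadata only and
#' never the motion. One motion trajectory (including motor positioning
#' errors) is built per participant; each condition re-records it under
#' independent measurement noise, as three separate physical recordings
#' would. With `condition_independent_noise = TRUE` the noise seed is also
#' shared and the three streams are bit-identical.
#'
#' Each participant's stream starts with a flagged transition move from
#' the screen centre to the first plan target, mirroring the repositioning
#' saccades between participants that the exclusion filter must drop.
#'
#' @param n_participants,n_saccades experiment size per condition
#' @param conditions a data.frame of conditions ([brightness_conditions()])
#' @param seed master integer seed; every participant/condition seed is
#'   derived from it
#' @param condition_independent_noise logical; share noise across
#'   conditions (default FALSE)
#' @param screen,camera,motor geometry and motor configuration
#' @param ... noise/pupil parameters passed to [render_stream()]
#' @return a list of class `experiment_sim`: per participant a list with
#'   the `plan` and one `sample_stream` per condition;
#'   `attr(, "planned_saccades")` is `n_participants * n_saccades * k`
#' @export
simulate_experiment <- function(n_participants = 200, n_saccades = 200,
                                conditions = brightness_conditions(),
                                seed = 1,
                                condition_independent_noise = FALSE,
                                screen = screen_geometry(),
                                camera = camera_geometry(),
                                motor = motor_config(), ...) {
  stopifnot(n_participants >= 1, n_saccades >= 1, nrow(conditions) >= 1)
  home <- screen$center_px
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    plan <- plan_random_saccades(n_saccades, seed = child_seed(seed, p, 1L),
                                 screen = screen)
    motion <- build_motion(plan, screen, motor,
                           seed = child_seed(seed, p, 2L), home_px = home)
    streams <- vector("list", nrow(conditions))
    names(streams) <- conditions$name
    for (ci in seq_len(nrow(conditions))) {
      ns <- if (condition_independent_noise) child_seed(seed, p, 3L)
            else child_seed(seed, p, 3L, ci)
      st <- render_stream(motion, screen, camera, seed = ns, ...)
      attr(st, "condition") <- conditions$name[ci]
      attr(st, "participant") <- p
      streams[[ci]] <- st
    }
    out[[p]] <- list(participant = p, plan = plan, streams = streams)
  }
  structure(out, class = "experiment_sim",
            planned_saccades = n_participants * n_saccades * nrow(conditions),
            seed = as.integer(seed), conditions = conditions)
}

#' @export
print.sample_stream <- function(x, ...) {
  tr <- attr(x, "truth")
  cat("<sample_stream> ", nrow(x), " samples @ ", attr(x, "fs_hz"),
      " Hz (", sprintf("%.2f", nrow(x) / attr(x, "fs_hz")), " s)\n", sep = "")
  if (!is.null(tr))
    cat("  planned moves: ", nrow(tr),
        if (any(tr$is_transition)) " (incl. transition)", "\n", sep = "")
  cond <- attr(x, "condition")
  if (!is.null(cond)) cat("  condition: ", cond, "\n", sep = "")
  cat("  position noise SD: ", attr(x, "noise_sd_deg"), " deg\n", sep = "")
  invisible(x)
}

#' @export
print.experiment_sim <- function(x, ...) {
  cat("<experiment_sim> ", length(x), " participants x ",
      nrow(attr(x, "conditions")), " conditions, ",
      attr(x, "planned_saccades"), " planned saccades (seed ",
      attr(x, "seed"), ")\n", sep = "")
  invisible(x)
}

#' Plot a sample stream
#'
#' Temporal view of a recording: gaze x/y position (pixels) and pupil
#' size (arbitrary units) against time.
#'
#' @param x a `sample_stream`
#' @param ... further arguments passed to [graphics::plot()]
#' @export
plot.sample_stream <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t_ms, x$x_px, type = "l", col = "firebrick",
                 xlab = "time [ms]", ylab = "gaze [px]",
                 ylim = range(c(x$x_px, x$y_px)), ...)
  graphics::lines(x$t_ms, x$y_px, col = "forestgreen")
  graphics::legend("topright", c("x", "y"), lty = 1, bty = "n",
                   col = c("firebrick", "forestgreen"))
  graphics::plot(x$t_ms, x$pupil_au, type = "l", col = "steelblue",
                 xlab = "time [ms]", ylab = "pupil [a.u.]")
  invisible(x)
}
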