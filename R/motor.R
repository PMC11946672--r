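#' Stepper-gimbal motor configuration
#'
#' Kinematic constants of the two-axis stepper gimbal driving the
#' artificial eye. The defaults describe 1.8-degree NEMA 17 motors in
#' 16-microstepping mode (0.1125 deg/microstep), driven at up to 3200
#' pulses per second (360 deg/s) with an acceleration ramp of 80,000
#' pulses/s^2 (9000 deg/s^2). The positioning error of the drive chain
#' (potentiometer, ADC, driver) is bounded by +-2 microsteps (+-0.225 deg).
#'
#' @param full_step_deg full-step angle, degrees
#' @param microstep_factor microstepping subdivision
#' @param v_max_pps maximum pulse rate, pulses/s
#' @param accel_pps2 acceleration, pulses/s^2
#' @param quant_error_microsteps positioning-error bound, microsteps
#' @param backlash_deg per-axis backlash dead band on direction reversal,
#'   degrees (default 0: the hinge backlash is acknowledged but unquantified)
#' @return an object of class `motor_config` with derived fields
#'   `resolution_deg`, `v_max_dps` and `accel_dps2`
#' @export
motor_config <- function(full_step_deg = 1.8, microstep_factor = 16,
                         v_max_pps = 3200, accel_pps2 = 80000,
                         quant_error_microsteps = 2, backlash_deg = c(0, 0)) {
  if (any(c(full_step_deg, microstep_factor, v_max_pps, accel_pps2) <= 0))
    stop("motor constants must be positive")
  res <- microstep_resolution(full_step_deg, microstep_factor)
  structure(list(full_step_deg = full_step_deg,
                 microstep_factor = microstep_factor,
                 v_max_pps = v_max_pps,
                 accel_pps2 = accel_pps2,
                 quant_error_microsteps = quant_error_microsteps,
                 backlash_deg = rep_len(backlash_deg, 2),
                 resolution_deg = res,
                 v_max_dps = pps_to_dps(v_max_pps, res),
                 accel_dps2 = pps_to_dps(accel_pps2, res)),
            class = "motor_config")
}

#' Angular trajectory of a single-axis gimbal move
#'
#' Closed-form trapezoidal velocity profile sampled on the 1 kHz tracker
#' clock: the axis accelerates at `accel_dps2` toward the velocity ceiling
#' `v_max_dps` and decelerates symmetrically. Moves shorter than
#' `v_max^2 / accel` (14.4 degrees at the defaults) never reach the ceiling
#' and follow a triangular profile with peak velocity `sqrt(accel * d)`.
#' The commanded displacement is snapped to the microstep lattice, so the
#' realized displacement differs from `delta_deg` by at most half a
#' microstep; the final sample sits exactly on the snapped target.
#'
#' @param delta_deg signed commanded rotation, degrees
#' @param cfg a [motor_config()]
#' @param fs_hz sample rate of the returned trajectory, Hz
#' @return numeric vector of angular positions (degrees, relative to the
#'   start) at 1/fs_hz intervals, excluding the start sample; `numeric(0)`
#'   for a move smaller than half a microstep
#' @export
motor_move_profile <- function(delta_deg, cfg = motor_config(), fs_hz = 1000) {
  res <- cfg$resolution_deg
  d_cmd <- round(delta_deg / res) * res
  if (d_cmd == 0) return(numeric(0))
  s <- sign(d_cmd)
  d <- abs(d_cmd)
  a <- cfg$accel_dps2
  vmax <- cfg$v_max_dps
  if (d >= vmax^2 / a) {       # trapezoid: accel, plateau, decel
    t1 <- vmax / a
    tc <- (d - vmax^2 / a) / vmax
  } else {                     # triangle: peak velocity sqrt(a d)
    t1 <- sqrt(d / a)
    tc <- 0
  }
  T_tot <- 2 * t1 + tc
  t <- seq_len(ceiling(T_tot * fs_hz)) / fs_hz
  pos <- ifelse(t <= t1, 0.5 * a * t^2,
         ifelse(t <= t1 + tc, 0.5 * a * t1^2 + a * t1 * (t - t1),
         ifelse(t < T_tot, d - 0.5 * a * (T_tot - t)^2, d)))
  s * pos
}

#' Superpose two single-axis trajectories into a 2-D gaze trajectory
#'
#' The gimbal's intersecting-axis hinge makes the two rotations
#' independent, so oblique moves are the component-wise superposition of
#' the per-axis profiles; combined speed is `sqrt(vx^2 + vy^2)`. The
#' shorter trajectory is padded with its terminal value (or 0 if empty).
#'
#' @param x_traj,y_traj per-axis position vectors from
#'   [motor_move_profile()], on a common sample clock
#' @return matrix with columns `theta_x`, `theta_y`
#' @export
superpose_axes <- function(x_traj, y_traj) {
  n <- max(length(x_traj), length(y_traj))
  pad <- function(v) {
    if (length(v) == 0) rep(0, n)
    else c(v, rep(v[length(v)], n - length(v)))
  }
  cbind(theta_x = pad(x_traj), theta_y = pad(y_traj))
}
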