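#' Screen geometry of the stimulus display
#'
#' Physical and pixel dimensions of the display plus the eye-to-screen
#' viewing distance. Defaults describe a 24-inch 1920 x 1080 monitor
#' (531.36 mm x 298.89 mm) viewed from 927 mm, i.e. the recommended
#' >= 1.75 x display-width tracking distance.
#'
#' The monitor has square pixels: the horizontal pitch (width_mm/width_px)
#' and vertical pitch agree to well under 1e-4 mm. All pixel-to-metric
#' conversions use the horizontal pitch.
#'
#' @param width_mm,height_mm physical display size in mm
#' @param width_px,height_px display resolution in pixels
#' @param viewing_distance_mm eye-to-screen distance in mm
#' @return an object of class `screen_geometry`
#' @export
screen_geometry <- function(width_mm = 531.36, height_mm = 298.89,
                            width_px = 1920L, height_px = 1080L,
                            viewing_distance_mm = 927) {
  vals <- c(width_mm, height_mm, width_px, height_px, viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen geometry fields must be strictly positive")
  pitch_x <- width_mm / width_px
  pitch_y <- height_mm / height_px
  if (abs(pitch_x - pitch_y) > 1e-4)
    warning("non-square pixels: horizontal pitch used for both axes")
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 viewing_distance_mm = viewing_distance_mm,
                 pitch_mm = pitch_x,
                 center_px = c(width_px / 2, height_px / 2)),
            class = "screen_geometry")
}

#' Tracker camera geometry
#'
#' Position of the tracker's camera lens relative to the centre of the
#' (artificial) eye, in a right-handed frame with x rightward, y downward
#' and z pointing from the eye toward the screen/camera. A desktop-mounted
#' tracker sits below the screen, slightly left of and below the eye; the
#' default offset of (-80, +130, +530) mm reproduces the observed ordering
#' of apparent pupil area with gaze direction (largest looking left and
#' down) under the cosine foreshortening model of [apparent_pupil_area()].
#'
#' @param offset_mm length-3 numeric, eye-to-lens vector in mm
#' @param eye_height_mm eye height above the table, mm
#' @return an object of class `camera_geometry`
#' @export
camera_geometry <- function(offset_mm = c(-80, 130, 530),
                            eye_height_mm = 290) {
  if (length(offset_mm) != 3 || any(!is.finite(offset_mm)))
    stop("offset_mm must be a finite 3-vector")
  if (offset_mm[3] <= 0)
    stop("camera must be in front of the eye (positive z offset)")
  structure(list(offset_mm = as.numeric(offset_mm),
                 eye_height_mm = eye_height_mm,
                 unit = offset_mm / sqrt(sum(offset_mm^2))),
            class = "camera_geometry")
}

#' Laser-mirror projection rig
#'
#' Geometry of the laser validation setup: a canvas with a central laser
#' diode faces the eye, which carries a small front-surface mirror. The
#' reflected spot displacement on the canvas magnifies the eye rotation.
#' Pattern steps are eight microsteps, i.e. 0.9 degrees of eye rotation.
#'
#' @param canvas_distance_mm eye-to-canvas distance, mm
#' @param canvas_width_mm,canvas_height_mm canvas size, mm
#' @param step_deg eye rotation per pattern step, degrees
#' @return an object of class `laser_rig`
#' @export
laser_rig <- function(canvas_distance_mm = 700, canvas_width_mm = 679,
                      canvas_height_mm = 498, step_deg = 0.9) {
  vals <- c(canvas_distance_mm, canvas_width_mm, canvas_height_mm, step_deg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all laser rig fields must be strictly positive")
  structure(list(canvas_distance_mm = canvas_distance_mm,
                 canvas_width_mm = canvas_width_mm,
                 canvas_height_mm = canvas_height_mm,
                 step_deg = step_deg),
            class = "laser_rig")
}

#' The three screen-brightness conditions
#'
#' Greyscale background/target RGB values and measured luminances of the
#' dark, medium and light conditions, with their Weber contrasts computed
#' by [weber_contrast()]. The artificial eye is blind, so by construction
#' the condition is metadata only: it never alters the motion (the null
#' model the brightness analyses test).
#'
#' @return a data.frame with one row per condition
#' @export
brightness_conditions <- function() {
  out <- data.frame(
    name = c("dark", "medium", "light"),
    bg_rgb = c(20L, 100L, 240L),
    target_rgb = c(0L, 43L, 95L),
    L_bg = c(2.74, 47.09, 232.03),
    L_target = c(0.89, 6.83, 40.24),
    stringsAsFactors = FALSE
  )
  out$C_W <- weber_contrast(out$L_bg, out$L_target)
  out
}

#' Weber contrast of a dark target on a brighter background
#'
#' `(L_bg - L_target) / L_bg`, dimensionless; lies in `[0, 1]` whenever the
#' target is no brighter than the background.
#'
#' @param L_bg background luminance, cd/m^2 (must be positive)
#' @param L_target target luminance, cd/m^2
#' @return Weber contrast (vectorized)
#' @export
weber_contrast <- function(L_bg, L_target) {
  if (any(L_bg <= 0)) stop("background luminance must be positive")
  (L_bg - L_target) / L_bg
}

#' Convert a signed pixel offset to millimetres
#'
#' Linear in the offset; uses the horizontal pixel pitch
#' (`width_mm / width_px`).
#'
#' @param offset_px signed pixel offset (vectorized)
#' @param screen a [screen_geometry()]
#' @return signed offset in mm
#' @export
px_to_mm <- function(offset_px, screen = screen_geometry()) {
  stopifnot(inherits(screen, "screen_geometry"))
  offset_px * screen$pitch_mm
}

#' Convert a millimetre offset to degrees of visual angle
#'
#' `atan(offset / distance)` in degrees: an odd, monotone function of the
#' offset, evaluated as the angle subtended at the eye by a point displaced
#' from the line-of-sight foot point.
#'
#' @param offset_mm signed offset in mm (vectorized)
#' @param distance_mm viewing distance in mm (positive)
#' @return signed angle in degrees
#' @export
mm_to_deg <- function(offset_mm, distance_mm) {
  if (any(distance_mm <= 0)) stop("distance must be positive")
  atan(offset_mm / distance_mm) * 180 / pi
}

#' Convert a signed pixel offset to degrees of visual angle
#'
#' Composition of [px_to_mm()] and [mm_to_deg()] at the screen's viewing
#' distance — the conversion chain behind the paired px/mm/degree rows of
#' accuracy and precision tables.
#'
#' @inheritParams px_to_mm
#' @return signed angle in degrees
#' @export
px_to_deg <- function(offset_px, screen = screen_geometry()) {
  mm_to_deg(px_to_mm(offset_px, screen), screen$viewing_distance_mm)
}

#' Angular resolution of a microstepped stepper motor
#'
#' @param full_step_deg full-step angle, degrees (1.8 for a typical NEMA 17)
#' @param microstep_factor microstepping subdivision (16 here)
#' @return degrees per microstep
#' @export
microstep_resolution <- function(full_step_deg = 1.8, microstep_factor = 16) {
  if (any(full_step_deg <= 0) || any(microstep_factor <= 0))
    stop("full step and microstep factor must be positive")
  full_step_deg / microstep_factor
}

#' Convert a stepper pulse rate to angular velocity
#'
#' One pulse advances one microstep, so deg/s = pps x deg/microstep.
#'
#' @param pulses_per_second pulse rate (pps)
#' @param resolution_deg degrees per microstep, from [microstep_resolution()]
#' @return angular speed in deg/s
#' @export
pps_to_dps <- function(pulses_per_second, resolution_deg = microstep_resolution()) {
  pulses_per_second * resolution_deg
}

#' Worst-case positioning error of the drive chain
#'
#' @param n_microsteps error bound in microsteps (2 for the potentiometer +
#'   ADC + driver chain of the gimbal)
#' @param resolution_deg degrees per microstep
#' @return error bound in degrees
#' @export
positioning_error <- function(n_microsteps = 2, resolution_deg = microstep_resolution()) {
  if (any(n_microsteps < 0)) stop("n_microsteps must be non-negative")
  n_microsteps * resolution_deg
}

#' Laser-spot displacement on the canvas for an eye rotation
#'
#' A mirror on the eye reflects the central laser back onto the canvas;
#' specular reflection doubles the rotation angle, magnifying the motion.
#' The default `"doubled_tangent"` model applies the doubling to the
#' tangent displacement, `2 * D * tan(theta)` — the convention used when
#' comparing planned and photographed patterns. The physically exact
#' reflection, `D * tan(2 * theta)`, is available as `model = "specular"`;
#' the two differ by ~2 cm at the outermost 13.5-degree pattern coordinate.
#'
#' @param eye_angle_deg eye rotation, degrees; must satisfy
#'   `abs(eye_angle_deg) < 45`
#' @param rig a [laser_rig()]
#' @param model `"doubled_tangent"` (default) or `"specular"`
#' @return signed canvas displacement in mm (odd in the angle)
#' @export
laser_displacement <- function(eye_angle_deg, rig = laser_rig(),
                               model = c("doubled_tangent", "specular")) {
  model <- match.arg(model)
  if (any(abs(eye_angle_deg) >= 45))
    stop("eye angle out of range: |angle| must be < 45 degrees")
  th <- eye_angle_deg * pi / 180
  switch(model,
         doubled_tangent = 2 * rig$canvas_distance_mm * tan(th),
         specular = rig$canvas_distance_mm * tan(2 * th))
}

#' Apparent (foreshortened) pupil area for a gaze direction
#'
#' A circular pupil imaged off-axis appears elliptical; under a Lambert-style
#' projection its apparent area is the true area times the cosine of the
#' angle gamma between the gaze direction (pupil normal) and the eye-to-camera
#' direction. The area is maximal when looking straight into the camera,
#' strictly decreasing in gamma, and zero at or beyond 90 degrees (pupil edge-on
#' or invisible). Depending only on the dot product, it is invariant under
#' rotation of the gaze about the eye-to-camera axis.
#'
#' @param gaze_dir unit 3-vector (or n x 3 matrix of unit rows) of gaze
#'   direction(s) in the camera frame (x right, y down, z forward)
#' @param camera a [camera_geometry()]
#' @param base_area true pupil area in arbitrary tracker units (positive)
#' @return apparent area(s), same units as `base_area`
#' @export
apparent_pupil_area <- function(gaze_dir, camera = camera_geometry(),
                                base_area = 2888.94) {
  if (base_area <= 0) stop("base_area must be positive")
  if (is.null(dim(gaze_dir))) gaze_dir <- matrix(gaze_dir, nrow = 1)
  nrm <- sqrt(rowSums(gaze_dir^2))
  if (any(abs(nrm - 1) > 1e-6)) gaze_dir <- gaze_dir / nrm
  cosg <- as.vector(gaze_dir %*% camera$unit)
  base_area * pmax(cosg, 0)
}

#' Gaze angles of a screen target
#'
#' Maps screen pixel coordinates to horizontal/vertical gaze angles for an
#' eye on the screen-centre normal at the viewing distance:
#' `theta = atan(offset_from_centre_mm / viewing_distance_mm)` per axis.
#' The screen centre maps to (0, 0); x is rightward, y downward (positive
#' vertical angle = looking down). Exact inverse of [gaze_to_screen_px()].
#'
#' @param target_px numeric length-2 `(x, y)` or an n x 2 matrix of pixel
#'   coordinates (0-based, origin top-left)
#' @param screen a [screen_geometry()]
#' @return matrix (n x 2) of angles `(theta_x, theta_y)` in degrees
#' @export
target_to_gaze_angles <- function(target_px, screen = screen_geometry()) {
  if (is.null(dim(target_px))) target_px <- matrix(target_px, ncol = 2)
  if (any(target_px[, 1] < 0 | target_px[, 1] > screen$width_px |
          target_px[, 2] < 0 | target_px[, 2] > screen$height_px))
    warning("target outside screen bounds; angles computed anyway")
  off_mm <- sweep(target_px, 2, screen$center_px) * screen$pitch_mm
  th <- atan(off_mm / screen$viewing_distance_mm) * 180 / pi
  colnames(th) <- c("theta_x", "theta_y")
  th
}

#' Screen pixel coordinates of a gaze direction
#'
#' Inverse of [target_to_gaze_angles()]: maps `(theta_x, theta_y)` gaze
#' angles (degrees) back to screen pixels.
#'
#' @param angles_deg length-2 `(theta_x, theta_y)` or n x 2 matrix, degrees
#' @param screen a [screen_geometry()]
#' @return matrix (n x 2) of pixel coordinates `(x_px, y_px)`
#' @export
gaze_to_screen_px <- function(angles_deg, screen = screen_geometry()) {
  if (is.null(dim(angles_deg))) angles_deg <- matrix(angles_deg, ncol = 2)
  off_mm <- tan(angles_deg * pi / 180) * screen$viewing_distance_mm
  px <- sweep(off_mm / screen$pitch_mm, 2, screen$center_px, `+`)
  colnames(px) <- c("x_px", "y_px")
  px
}
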