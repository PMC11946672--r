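#' Planned coordinates of the 13-point calibration grid
#'
#' The 13 screen-pixel target positions used for tracker calibration and
#' for the accuracy/precision runs: centre, the four edge midpoints, the
#' four corners and four inner diagonal points, on a 1920 x 1080 display.
#'
#' @return an n x 2 matrix of planned `(x_px, y_px)` coordinates with
#'   class attribute `pattern` and name `"grid13"`
#' @export
calibration_grid <- function() {
  tx <- c(960, 960, 960, 115, 1805, 115, 1805, 115, 1805,
          538, 1382, 538, 1382)
  ty <- c(540, 92, 988, 540, 540, 92, 92, 988, 988,
          316, 316, 764, 764)
  pattern("grid13", cbind(x_px = tx, y_px = ty))
}

pattern <- function(name, targets, screen = screen_geometry()) {
  stopifnot(is.matrix(targets), ncol(targets) == 2)
  if (any(targets[, 1] < 0 | targets[, 1] > screen$width_px |
          targets[, 2] < 0 | targets[, 2] > screen$height_px))
    stop("pattern targets must lie within the screen")
  structure(targets, pattern_name = name, class = c("pattern", class(targets)))
}

#' Built-in stimulus patterns
#'
#' The scripted movement patterns used in the accuracy/precision runs:
#' single horizontal and vertical lines through the screen centre (saccades
#' of varying length along one axis), multiple horizontal/vertical lines
#' covering the screen, a diagonal cross, and the 13-point calibration
#' grid. Random-saccade sequences come from [plan_random_saccades()].
#'
#' @param name one of `"h_line"`, `"v_line"`, `"multi_h"`, `"multi_v"`,
#'   `"cross"`, `"grid13"`
#' @param screen a [screen_geometry()]
#' @param margin_frac fractional screen margin kept free per side
#' @return a pattern matrix of `(x_px, y_px)` targets
#' @export
pattern_targets <- function(name = c("grid13", "h_line", "v_line",
                                     "multi_h", "multi_v", "cross"),
                            screen = screen_geometry(),
                            margin_frac = 0.06) {
  name <- match.arg(name)
  if (name == "grid13") return(calibration_grid())
  W <- screen$width_px; H <- screen$height_px
  cx <- screen$center_px[1]; cy <- screen$center_px[2]
  xs <- seq(W * margin_frac, W * (1 - margin_frac), length.out = 7)
  ys <- seq(H * margin_frac, H * (1 - margin_frac), length.out = 5)
  tg <- switch(name,
    h_line = cbind(xs, rep(cy, length(xs))),
    v_line = cbind(rep(cx, length(ys)), ys),
    multi_h = do.call(rbind, lapply(ys[c(1, 3, 5)], function(y)
      cbind(xs, rep(y, length(xs))))),
    multi_v = do.call(rbind, lapply(xs[c(1, 4, 7)], function(x)
      cbind(rep(x, length(ys)), ys))),
    cross = rbind(cbind(xs, seq(ys[1], ys[5], length.out = 7)),
                  cbind(xs, seq(ys[5], ys[1], length.out = 7)))
  )
  colnames(tg) <- c("x_px", "y_px")
  pattern(name, tg, screen)
}

#' Plan a random-saccade trial sequence
#'
#' Draws `n + 1` screen targets such that every consecutive pair is
#' separated by a saccade amplitude (Euclidean distance in gaze-angle
#' space) uniform in `amp_range_deg`, in a direction uniform on the
#' circle, with every target inside the screen shrunk by `margin_frac`
#' per side so overshoots cannot leave the trackable area. The same seed
#' reproduces the identical plan; across brightness conditions one
#' participant reuses one plan.
#'
#' @param n number of planned saccades (>= 1)
#' @param amp_range_deg amplitude range in degrees of visual angle
#' @param margin_frac fractional screen margin excluded per side
#' @param seed integer RNG seed
#' @param screen a [screen_geometry()]
#' @param max_tries rejection-sampling bound per target
#' @return an n+1 x 2 matrix of `(x_px, y_px)` targets with attributes
#'   `amplitudes_deg` (planned consecutive amplitudes) and `seed`
#' @export
plan_random_saccades <- function(n, amp_range_deg = c(4.5, 14.1),
                                 margin_frac = 0.10, seed = 1,
                                 screen = screen_geometry(),
                                 max_tries = 500) {
  stopifnot(n >= 1, amp_range_deg[1] > 0, amp_range_deg[2] >= amp_range_deg[1])
  lo_px <- c(screen$width_px, screen$height_px) * margin_frac
  hi_px <- c(screen$width_px, screen$height_px) * (1 - margin_frac)
  box <- target_to_gaze_angles(rbind(lo_px, hi_px), screen)
  set.seed(as.integer(seed))
  th <- matrix(NA_real_, n + 1, 2)
  th[1, ] <- c(stats::runif(1, box[1, 1], box[2, 1]),
               stats::runif(1, box[1, 2], box[2, 2]))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      amp <- stats::runif(1, amp_range_deg[1], amp_range_deg[2])
      phi <- stats::runif(1, 0, 2 * pi)
      cand <- th[i, ] + amp * c(cos(phi), sin(phi))
      if (cand[1] >= box[1, 1] && cand[1] <= box[2, 1] &&
          cand[2] >= box[1, 2] && cand[2] <= box[2, 2]) {
        th[i + 1, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place target ", i,
           ": amplitude range infeasible within screen margin")
  }
  px <- gaze_to_screen_px(th, screen)
  amps <- sqrt(rowSums((th[-1, , drop = FALSE] -
                          th[-(n + 1), , drop = FALSE])^2))
  structure(pattern("random", px, screen),
            amplitudes_deg = amps, seed = as.integer(seed))
}
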