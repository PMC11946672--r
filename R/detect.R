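#' Savitzky-Golay velocity of a gaze sample stream
#'
#' Converts gaze positions to degrees of visual angle (via the screen
#' geometry) and differentiates each axis with a Savitzky-Golay FIR
#' filter — by default 3rd order over a seven-sample window, the standard
#' choice for 1000 Hz gaze data. The filter reproduces the derivative of
#' polynomials up to its order exactly on interior samples, so a linear
#' position ramp of k deg/ms yields exactly 1000 k deg/s.
#'
#' @param stream a `sample_stream`, or any data.frame with `x_px`/`y_px`
#' @param order polynomial order of the filter
#' @param window filter window length in samples (odd, > order)
#' @param screen a [screen_geometry()]; defaults to the stream's own
#' @return a data.frame of class `velocity_signal` with columns `t_ms`,
#'   `theta_x`, `theta_y` (positions, deg), `vx`, `vy` (per-axis velocity,
#'   deg/s) and `v` (combined speed `sqrt(vx^2 + vy^2)`)
#' @export
sg_velocity <- function(stream, order = 3, window = 7,
                        screen = attr(stream, "screen")) {
  if (is.null(screen)) screen <- screen_geometry()
  if (nrow(stream) < window)
    stop("stream shorter than the filter window (", window, " samples)")
  fs <- attr(stream, "fs_hz")
  if (is.null(fs)) fs <- 1000
  th <- target_to_gaze_angles(cbind(stream$x_px, stream$y_px), screen)
  vx <- signal::sgolayfilt(th[, 1], p = order, n = window, m = 1, ts = 1 / fs)
  vy <- signal::sgolayfilt(th[, 2], p = order, n = window, m = 1, ts = 1 / fs)
  out <- data.frame(t_ms = stream$t_ms, theta_x = th[, 1], theta_y = th[, 2],
                    vx = vx, vy = vy, v = sqrt(vx^2 + vy^2))
  structure(out, class = c("velocity_signal", "data.frame"), fs_hz = fs)
}

#' Adaptive estimate of the velocity-noise level
#'
#' Data-driven noise estimation for velocity-threshold saccade detection:
#' starting from `start_threshold_dps`, the noise SD `sigma` of each axis
#' is the SD of velocity samples below the current threshold, the
#' threshold is updated to `mean + 6 sigma` of those samples, and the two
#' steps are iterated until the threshold moves by less than `tol` deg/s.
#' The update is accepted only while it lowers the threshold: the scheme
#' converges from above onto the noise floor, and on recordings with a
#' high movement duty cycle (scripted saccades every few hundred ms) an
#' increasing update would only sweep movement samples into the estimate,
#' so the iteration stops at the first non-decreasing update instead.
#' The detection threshold is then `eta = lambda * sigma` with
#' `lambda = 3`. An all-zero (noiseless) signal gets a floor of 1e-6 deg/s
#' so the threshold never collapses to zero.
#'
#' @param velocity a [sg_velocity()] result
#' @param start_threshold_dps initial threshold, deg/s
#' @param lambda threshold multiplier
#' @param tol convergence tolerance on the threshold, deg/s
#' @param max_iter iteration cap
#' @return an object of class `noise_estimate` with `sigma_x`, `sigma_y`,
#'   `eta_x`, `eta_y`, the combined detection threshold
#'   `eta = lambda * max(sigma_x, sigma_y)` and the iteration counts
#' @export
estimate_noise_sigma <- function(velocity, start_threshold_dps = 100,
                                 lambda = 3, tol = 1, max_iter = 100) {
  if (nrow(velocity) == 0) stop("empty velocity signal")
  one_axis <- function(v) {
    T_cur <- start_threshold_dps
    sigma <- NA_real_
    for (it in seq_len(max_iter)) {
      sel <- abs(v) < T_cur
      if (sum(sel) < 2) {
        sigma <- 1e-6
        break
      }
      sigma <- max(stats::sd(v[sel]), 1e-6)
      T_new <- mean(v[sel]) + 6 * sigma
      if (T_new >= T_cur || abs(T_new - T_cur) < tol) break
      T_cur <- T_new
    }
    list(sigma = sigma, iterations = it)
  }
  ax <- one_axis(velocity$vx)
  ay <- one_axis(velocity$vy)
  structure(list(sigma_x = ax$sigma, sigma_y = ay$sigma,
                 eta_x = lambda * ax$sigma, eta_y = lambda * ay$sigma,
                 eta = lambda * max(ax$sigma, ay$sigma),
                 lambda = lambda,
                 iterations = c(x = ax$iterations, y = ay$iterations)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "<noise_estimate> sigma = (%.3g, %.3g) deg/s, eta = %.3g deg/s (lambda = %g)\n",
    x$sigma_x, x$sigma_y, x$eta, x$lambda))
  invisible(x)
}

#' Detect saccades as velocity outliers
#'
#' A saccade is a maximal run of at least `min_run` (default six)
#' consecutive samples whose combined speed exceeds the adaptive
#' threshold `eta` from [estimate_noise_sigma()]. Onset and offset are
#' the first and last sample of the supra-threshold run; events are
#' non-overlapping and time-ordered by construction. Runs shorter than
#' `min_run` are never reported.
#'
#' @param velocity a [sg_velocity()] result
#' @param noise a [estimate_noise_sigma()] result (estimated on the same
#'   signal), or a single numeric threshold in deg/s
#' @param min_run minimum run length in samples
#' @return a data.frame with one row per event: `onset_ms`, `offset_ms`
#'   and the sample indices `onset_idx`, `offset_idx` (1-based); zero rows
#'   if nothing exceeds the threshold
#' @export
detect_saccades <- function(velocity, noise, min_run = 6) {
  eta <- if (is.numeric(noise)) noise[1] else noise$eta
  above <- velocity$v > eta
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  data.frame(onset_ms = velocity$t_ms[starts[keep]],
             offset_ms = velocity$t_ms[ends[keep]],
             onset_idx = starts[keep], offset_idx = ends[keep])
}

#' Amplitude, peak velocity and direction of detected saccades
#'
#' Amplitude is the angular distance between gaze at onset and offset
#' (`sqrt(dtheta_x^2 + dtheta_y^2)`, degrees); peak velocity is the
#' maximum combined speed within the event; direction is the screen-up
#' convention angle of the displacement (0 = rightward, 90 = upward).
#' A zero-length displacement gets amplitude 0 and `NA` direction.
#'
#' @param events a [detect_saccades()] result
#' @param velocity the [sg_velocity()] signal the events were detected on
#' @return `events` with columns `amplitude_deg`, `peak_velocity_dps`,
#'   `direction_deg` appended
#' @export
saccade_metrics <- function(events, velocity) {
  n_ev <- nrow(events)
  amp <- pk <- dir <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    a <- events$onset_idx[i]
    b <- events$offset_idx[i]
    dx <- velocity$theta_x[b] - velocity$theta_x[a]
    dy <- velocity$theta_y[b] - velocity$theta_y[a]
    amp[i] <- sqrt(dx^2 + dy^2)
    pk[i] <- max(velocity$v[a:b])
    dir[i] <- if (amp[i] == 0) NA_real_
              else atan2(-dy, dx) * 180 / pi  # screen y is down
  }
  events$amplitude_deg <- amp
  events$peak_velocity_dps <- pk
  events$direction_deg <- dir
  events
}

#' Full event-detection chain for one stream
#'
#' Convenience wrapper: Savitzky-Golay velocity, adaptive noise estimate,
#' velocity-outlier detection, event metrics, then annotation against the
#' simulator's ground truth when available. Each event is matched to the
#' overlapping planned move (`move` column, `NA` for spurious events),
#' transition moves are flagged, and fragments — events truncated by the
#' stream end or separated from the next event by less than `frag_gap_ms`
#' (split saccades) — are marked.
#'
#' @param stream a `sample_stream`
#' @param lambda,min_run detection parameters
#' @param frag_gap_ms inter-event gap below which events count as fragments
#' @param ... passed to [sg_velocity()]
#' @return a data.frame of events with metrics, `move`, `is_transition`,
#'   `is_fragment`, and `participant`/`condition` tags when present; the
#'   velocity signal is attached as attribute `velocity`
#' @export
detect_events <- function(stream, lambda = 3, min_run = 6,
                          frag_gap_ms = 20, ...) {
  vel <- sg_velocity(stream, ...)
  noise <- estimate_noise_sigma(vel, lambda = lambda)
  ev <- saccade_metrics(detect_saccades(vel, noise, min_run), vel)
  n_ev <- nrow(ev)
  truth <- attr(stream, "truth")
  ev$move <- NA_integer_
  ev$is_transition <- FALSE
  if (!is.null(truth) && n_ev > 0) {
    for (i in seq_len(n_ev)) {
      ov <- which(truth$onset_ms <= ev$offset_ms[i] &
                    truth$offset_ms >= ev$onset_ms[i])
      if (length(ov) > 0) {
        ev$move[i] <- truth$move[ov[1]]
        ev$is_transition[i] <- any(truth$is_transition[ov])
      }
    }
  }
  ev$is_fragment <- FALSE
  if (n_ev > 0) {
    ev$is_fragment[n_ev] <- ev$offset_idx[n_ev] >= nrow(stream)
    if (n_ev > 1) {
      gap <- ev$onset_ms[-1] - ev$offset_ms[-n_ev]
      ev$is_fragment[which(gap < frag_gap_ms)] <- TRUE
      ev$is_fragment[which(gap < frag_gap_ms) + 1L] <- TRUE
    }
  }
  p <- attr(stream, "participant")
  cond <- attr(stream, "condition")
  ev$participant <- if (is.null(p)) NA_integer_ else p
  ev$condition <- if (is.null(cond)) NA_character_ else cond
  structure(ev, velocity = vel, noise = noise)
}

#' Extract fixation windows between saccades
#'
#' The complement of the detected events, trimmed by `guard_ms` at both
#' ends to shield the window statistics from transient samples around
#' onset/offset. Windows are matched to the stream's planned targets in
#' temporal order (the initial home fixation before a flagged transition
#' move is dropped); if the window count does not match the target count,
#' each window is matched to the nearest planned target and a warning
#' names the targets left without a stable window.
#'
#' @param stream a `sample_stream`
#' @param events a [detect_events()] (or [detect_saccades()]) result
#' @param guard_ms samples trimmed from each end of every window
#' @param targets_px optional n x 2 planned-target matrix; defaults to the
#'   stream's own plan
#' @return a data.frame with one row per fixation window: `target_index`,
#'   planned coordinates, window sample count `n`, means, SDs and
#'   within-window sums of squares of x/y (px), and `mean_pupil` (a.u.)
#' @export
extract_fixations <- function(stream, events, guard_ms = 20,
                              targets_px = attr(stream, "targets_px")) {
  n <- nrow(stream)
  if (nrow(events) > 0) {
    starts <- c(1L, events$offset_idx + 1L)
    ends <- c(events$onset_idx - 1L, n)
  } else {
    starts <- 1L
    ends <- n
  }
  starts <- starts + guard_ms
  ends <- ends - guard_ms
  ok <- ends - starts >= 0
  starts <- starts[ok]
  ends <- ends[ok]
  if (isTRUE(attr(stream, "has_transition")) && length(starts) > 0) {
    starts <- starts[-1]          # home fixation precedes the first target
    ends <- ends[-1]
  }
  nw <- length(starts)
  if (nw == 0) {
    warning("no stable fixation window found")
    return(data.frame())
  }
  stat <- function(v) {
    m <- sd <- ss <- numeric(nw)
    for (i in seq_len(nw)) {
      x <- v[starts[i]:ends[i]]
      m[i] <- mean(x)
      ss[i] <- sum((x - m[i])^2)
      sd[i] <- if (length(x) > 1) sqrt(ss[i] / (length(x) - 1)) else 0
    }
    list(mean = m, sd = sd, ss = ss)
  }
  sx <- stat(stream$x_px)
  sy <- stat(stream$y_px)
  sp <- stat(stream$pupil_au)
  out <- data.frame(target_index = seq_len(nw),
                    n = ends - starts + 1L,
                    mean_x = sx$mean, mean_y = sy$mean,
                    sd_x = sx$sd, sd_y = sy$sd,
                    ss_x = sx$ss, ss_y = sy$ss,
                    mean_pupil = sp$mean)
  if (!is.null(targets_px)) {
    tg <- unclass(targets_px)
    if (nw == nrow(tg)) {
      idx <- seq_len(nw)
    } else {
      idx <- vapply(seq_len(nw), function(i) {
        which.min((tg[, 1] - out$mean_x[i])^2 + (tg[, 2] - out$mean_y[i])^2)
      }, integer(1))
      missing <- setdiff(seq_len(nrow(tg)), idx)
      if (length(missing) > 0)
        warning("no stable fixation window for target(s) ",
                paste(missing, collapse = ", "), "; omitted")
    }
    out$target_index <- idx
    out$planned_x <- tg[idx, 1]
    out$planned_y <- tg[idx, 2]
  }
  out
}
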