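#' Accuracy table for a repeated target pattern
#'
#' Per planned coordinate and axis: the mean measured fixation position
#' over trials and its deviation from the planned true coordinate tau, in
#' pixels, millimetres and degrees of visual angle (the standard paired
#' px/mm/deg accuracy layout). Deviations are signed: measured minus
#' planned.
#'
#' @param fixations stacked [extract_fixations()] rows over trials (a
#'   `trial` column is optional and unused; grouping is by `target_index`)
#' @param grid planned-target matrix, e.g. [calibration_grid()]
#' @param screen a [screen_geometry()] for the unit conversions
#' @return a data.frame with one row per coordinate; coordinates never
#'   observed get `NA` rows and `absent = TRUE`
#' @export
accuracy_table <- function(fixations, grid = calibration_grid(),
                           screen = screen_geometry()) {
  tg <- unclass(grid)
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    f <- fixations[fixations$target_index == i, , drop = FALSE]
    if (nrow(f) == 0) {
      return(data.frame(target_index = i, planned_x = tg[i, 1],
                        planned_y = tg[i, 2], n_trials = 0L,
                        mean_x = NA_real_, mean_y = NA_real_,
                        dev_x_px = NA_real_, dev_y_px = NA_real_,
                        absent = TRUE))
    }
    data.frame(target_index = i, planned_x = tg[i, 1], planned_y = tg[i, 2],
               n_trials = nrow(f),
               mean_x = mean(f$mean_x), mean_y = mean(f$mean_y),
               dev_x_px = mean(f$mean_x) - tg[i, 1],
               dev_y_px = mean(f$mean_y) - tg[i, 2],
               absent = FALSE)
  })
  out <- do.call(rbind, rows)
  out$dev_x_mm <- px_to_mm(out$dev_x_px, screen)
  out$dev_y_mm <- px_to_mm(out$dev_y_px, screen)
  out$dev_x_deg <- px_to_deg(out$dev_x_px, screen)
  out$dev_y_deg <- px_to_deg(out$dev_y_px, screen)
  out
}

#' Precision table for a repeated target pattern
#'
#' Dispersion of the raw gaze samples about their per-trial fixation
#' means, pooled over trials per coordinate:
#' `sd = sqrt(sum(ss_trial) / sum(n_trial - 1))`, reported in pixels,
#' millimetres and degrees. Centring per trial isolates the tracker's
#' sample noise from the trial-to-trial repositioning scatter of the rig;
#' the between-trial SD of the fixation means is emitted alongside as
#' `sd_means_*`.
#'
#' @inheritParams accuracy_table
#' @return a data.frame with one row per coordinate
#' @export
precision_table <- function(fixations, grid = calibration_grid(),
                            screen = screen_geometry()) {
  tg <- unclass(grid)
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    f <- fixations[fixations$target_index == i, , drop = FALSE]
    if (nrow(f) < 2)
      stop("precision requires >= 2 trials per coordinate (coordinate ", i, ")")
    df <- sum(f$n - 1L)
    data.frame(target_index = i, planned_x = tg[i, 1], planned_y = tg[i, 2],
               n_trials = nrow(f), df = df,
               sd_x_px = sqrt(sum(f$ss_x) / df),
               sd_y_px = sqrt(sum(f$ss_y) / df),
               sd_means_x_px = stats::sd(f$mean_x),
               sd_means_y_px = stats::sd(f$mean_y))
  })
  out <- do.call(rbind, rows)
  out$sd_x_mm <- px_to_mm(out$sd_x_px, screen)
  out$sd_y_mm <- px_to_mm(out$sd_y_px, screen)
  out$sd_x_deg <- px_to_deg(out$sd_x_px, screen)
  out$sd_y_deg <- px_to_deg(out$sd_y_px, screen)
  out
}

#' Exclusion filter for detected saccades
#'
#' Drops, in order: (a) transition saccades (repositioning moves between
#' participants, whose random start positions can exceed the intended
#' amplitudes), (b) fragments (events split by tracking loss or truncated
#' at the stream end), and (c) events whose amplitude falls outside
#' `amp_range` — the planned 4.5-14.1 degree range widened by the 0.5 degree
#' tracker tolerance to 4-14.6 degrees, the regime where the main sequence
#' is linear.
#'
#' @param events a [detect_events()] result (rows may span participants
#'   and conditions)
#' @param amp_range retained amplitude range, degrees
#' @return a list with `events` (retained rows) and `log`, a data.frame
#'   of exclusion counts per reason plus `retained` and `total`
#' @export
exclusion_filter <- function(events, amp_range = c(4.0, 14.6)) {
  is_tr <- if ("is_transition" %in% names(events)) events$is_transition
           else rep(FALSE, nrow(events))
  is_fr <- if ("is_fragment" %in% names(events)) events$is_fragment
           else rep(FALSE, nrow(events))
  amp_out <- events$amplitude_deg < amp_range[1] |
    events$amplitude_deg > amp_range[2]
  drop_tr <- is_tr
  drop_fr <- !drop_tr & is_fr
  drop_amp <- !drop_tr & !drop_fr & amp_out
  keep <- !(drop_tr | drop_fr | drop_amp)
  list(events = events[keep, , drop = FALSE],
       log = data.frame(reason = c("transition", "fragment", "amplitude",
                                   "retained", "total"),
                        count = c(sum(drop_tr), sum(drop_fr), sum(drop_amp),
                                  sum(keep), nrow(events))))
}

#' Fit the saccadic main sequence
#'
#' Ordinary least squares of peak velocity on amplitude over the linear
#' regime of the main sequence, with the fitted peak velocity at a
#' 10-degree amplitude (`v10 = intercept + 10 * slope`) extracted as the
#' standard between-condition comparison statistic, and R-squared as the
#' explained-variance metric.
#'
#' @param saccades a data.frame with columns `amplitude_deg` and
#'   `peak_velocity_dps` (>= 3 rows, >= 2 distinct amplitudes)
#' @param at amplitude (degrees) at which the fitted peak velocity is
#'   reported (default 10)
#' @return an object of class `main_sequence`: coefficients
#'   `(intercept, slope)`, `v10`, `r_squared`, `n`, and the underlying
#'   [stats::lm] fit as `$model`
#' @export
main_sequence_fit <- function(saccades, at = 10) {
  if (nrow(saccades) < 3)
    stop("main sequence fit requires at least 3 saccades")
  if (length(unique(saccades$amplitude_deg)) < 2)
    stop("degenerate design: all saccades share one amplitude")
  fit <- stats::lm(peak_velocity_dps ~ amplitude_deg, data = saccades)
  cf <- stats::coef(fit)
  y <- saccades$peak_velocity_dps
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(coefficients = c(intercept = unname(cf[1]),
                                  slope = unname(cf[2])),
                 v10 = unname(cf[1] + at * cf[2]), at = at,
                 r_squared = r2,
                 n = nrow(saccades), model = fit),
            class = "main_sequence")
}

#' @export
print.main_sequence <- function(x, digits = 4, ...) {
  cat("Main sequence (peak velocity ~ amplitude), n =", x$n, "saccades\n")
  cat(sprintf("  intercept = %.*g deg/s, slope = %.*g deg/s per deg\n",
              digits, x$coefficients["intercept"],
              digits, x$coefficients["slope"]))
  cat(sprintf("  fitted peak velocity at %g deg: %.*g deg/s (R^2 = %.3f)\n",
              x$at, digits + 2, x$v10, x$r_squared))
  invisible(x)
}

#' @export
coef.main_sequence <- function(object, ...) object$coefficients

#' @export
predict.main_sequence <- function(object, amplitude_deg, ...) {
  if (missing(amplitude_deg)) return(stats::fitted(object$model))
  object$coefficients["intercept"] +
    object$coefficients["slope"] * amplitude_deg
}

#' @export
residuals.main_sequence <- function(object, ...) stats::residuals(object$model)

#' @export
summary.main_sequence <- function(object, ...) summary(object$model, ...)

#' Plot a fitted main sequence
#'
#' Amplitude versus peak velocity scatter with the OLS regression line
#' and the fitted value at the reference amplitude marked.
#'
#' @param x a `main_sequence` fit
#' @param ... passed to [graphics::plot()]
#' @export
plot.main_sequence <- function(x, ...) {
  d <- x$model$model
  graphics::plot(d$amplitude_deg, d$peak_velocity_dps,
                 xlab = "amplitude [deg]", ylab = "peak velocity [deg/s]",
                 pch = 16, col = grDevices::adjustcolor("grey30", 0.4), ...)
  graphics::abline(x$model, col = "firebrick", lwd = 2)
  graphics::points(x$at, x$v10, col = "firebrick", pch = 3, cex = 2)
  invisible(x)
}

#' Per-participant, per-condition fitted peak velocity at 10 degrees
#'
#' Fits the main sequence separately for every participant x condition
#' cell and pools all participants for a grand per-condition fit. The
#' participant x condition matrix of v10 values is the input for the
#' brightness repeated-measures ANOVA; participants with fewer than
#' `min_saccades` retained saccades (or a degenerate amplitude design) in
#' any condition are excluded with a warning, mirroring the handling of
#' empty recordings.
#'
#' @param events retained (filtered) events with `participant`,
#'   `condition`, `amplitude_deg`, `peak_velocity_dps`
#' @param conditions condition level order (default: order of appearance)
#' @param min_saccades minimum retained saccades per cell
#' @return a list with `v10` (participants x conditions matrix), `grand`
#'   (named vector of pooled per-condition v10), `fits` (pooled
#'   [main_sequence_fit()] per condition) and `excluded` (participant ids)
#' @export
per_condition_v10 <- function(events, conditions = unique(events$condition),
                              min_saccades = 3) {
  parts <- sort(unique(events$participant))
  v10 <- matrix(NA_real_, length(parts), length(conditions),
                dimnames = list(parts, conditions))
  for (pi in seq_along(parts)) {
    for (ci in seq_along(conditions)) {
      cell <- events[events$participant == parts[pi] &
                       events$condition == conditions[ci], , drop = FALSE]
      if (nrow(cell) >= min_saccades &&
          length(unique(cell$amplitude_deg)) >= 2)
        v10[pi, ci] <- main_sequence_fit(cell)$v10
    }
  }
  bad <- apply(v10, 1, anyNA)
  if (any(bad)) {
    warning(sum(bad), " participant(s) excluded: too few retained saccades")
    v10 <- v10[!bad, , drop = FALSE]
  }
  fits <- lapply(conditions, function(cn)
    main_sequence_fit(events[events$condition == cn, , drop = FALSE]))
  names(fits) <- conditions
  list(v10 = v10,
       grand = vapply(fits, function(f) f$v10, numeric(1)),
       fits = fits,
       excluded = parts[bad])
}
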