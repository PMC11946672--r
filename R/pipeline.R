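#' Run configuration for the end-to-end analyses
#'
#' Bundles every tunable of the simulation and analysis chain with the
#' rig's defaults: screen/camera/motor geometry, noise levels, experiment
#' sizes, the fixation duration, the amplitude exclusion window and the
#' master seed. Serializes losslessly to JSON via [save_config()] /
#' [load_config()].
#'
#' @param n_trials accuracy/precision trials of the calibration grid
#' @param n_participants,n_saccades brightness-experiment size
#' @param fixation_ms fixation duration per target, ms
#' @param noise_sd_deg position-noise SD, degrees
#' @param pupil_base_au true pupil area, tracker units
#' @param pupil_noise_au pupil measurement-noise SD, a.u.
#' @param amp_range retained saccade-amplitude range, degrees
#' @param seed master integer seed
#' @param condition_independent_noise share measurement noise across
#'   conditions (making condition streams bit-identical)
#' @param screen,camera,motor parameter lists overriding the geometry
#'   defaults (passed to [screen_geometry()], [camera_geometry()],
#'   [motor_config()])
#' @return an object of class `run_config`
#' @export
run_config <- function(n_trials = 100, n_participants = 200,
                       n_saccades = 200, fixation_ms = 300,
                       noise_sd_deg = 0.02, pupil_base_au = 2888.94,
                       pupil_noise_au = 2, amp_range = c(4.0, 14.6),
                       seed = 1, condition_independent_noise = FALSE,
                       screen = list(), camera = list(), motor = list()) {
  structure(list(n_trials = n_trials, n_participants = n_participants,
                 n_saccades = n_saccades, fixation_ms = fixation_ms,
                 noise_sd_deg = noise_sd_deg,
                 pupil_base_au = pupil_base_au,
                 pupil_noise_au = pupil_noise_au,
                 amp_range = amp_range, seed = as.integer(seed),
                 condition_independent_noise = condition_independent_noise,
                 screen = screen, camera = camera, motor = motor),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path JSON path
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  for (f in c("screen", "camera", "motor"))
    raw[[f]] <- as.list(raw[[f]])
  structure(raw, class = "run_config")
}

config_objects <- function(config) {
  list(screen = do.call(screen_geometry, config$screen),
       camera = do.call(camera_geometry, config$camera),
       motor = do.call(motor_config, config$motor))
}

#' Reproducibility manifest of a run
#'
#' Hash of the canonical JSON form of the configuration, the seed
#' registry and MD5 checksums of the produced output files: identical
#' configuration and seeds yield identical checksums.
#'
#' @param config a [run_config()]
#' @param files character vector of output file paths
#' @return a list with `config_hash`, `seed`, `checksums`, `version`
#' @export
run_manifest <- function(config, files = character()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  sums <- if (length(files) > 0) tools::md5sum(files) else character(0)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = config$seed,
       checksums = as.list(sums),
       version = as.character(utils::packageVersion("roboteye")))
}

# One participant of the brightness experiment: a reusable plan, one
# motion trajectory, and one rendered stream per condition.
simulate_participant <- function(p, seed, n_saccades, conditions, screen,
                                 camera, motor, fixation_ms = 300,
                                 condition_independent_noise = FALSE, ...) {
  plan <- plan_random_saccades(n_saccades, seed = child_seed(seed, p, 1L),
                               screen = screen)
  motion <- build_motion(plan, screen, motor, fixation_ms,
                         seed = child_seed(seed, p, 2L),
                         home_px = screen$center_px)
  streams <- lapply(seq_len(nrow(conditions)), function(ci) {
    ns <- if (condition_independent_noise) child_seed(seed, p, 3L)
          else child_seed(seed, p, 3L, ci)
    st <- render_stream(motion, screen, camera, seed = ns, ...)
    attr(st, "condition") <- conditions$name[ci]
    attr(st, "participant") <- p
    st
  })
  names(streams) <- conditions$name
  list(participant = p, plan = plan, streams = streams)
}

#' Accuracy and precision report for the calibration grid
#'
#' Simulates `n_trials` recordings of the 13-point calibration grid,
#' detects saccades, extracts fixation windows and tabulates accuracy
#' ([accuracy_table()]) and precision ([precision_table()]) in px, mm and
#' degrees. The per-trial fixation table (with pupil means) is kept for
#' the gaze-direction pupil analysis.
#'
#' @param config a [run_config()]
#' @param grid target pattern (default [calibration_grid()])
#' @param out_dir optional directory; when given, the tables, fixations
#'   and a [run_manifest()] are written as CSV/JSON
#' @return an object of class `accuracy_report`: `accuracy`, `precision`,
#'   `fixations` (stacked with `trial` column), `n_trials`, `config`
#' @export
run_accuracy_precision <- function(config = run_config(),
                                   grid = calibration_grid(),
                                   out_dir = NULL) {
  obj <- config_objects(config)
  fx_all <- vector("list", config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    st <- simulate_trial(grid, obj$screen, obj$camera, obj$motor,
                         fixation_ms = config$fixation_ms,
                         motion_seed = child_seed(config$seed, tr, 21L),
                         noise_seed = child_seed(config$seed, tr, 22L),
                         noise_sd_deg = config$noise_sd_deg,
                         pupil_base_au = config$pupil_base_au,
                         pupil_noise_au = config$pupil_noise_au)
    ev <- detect_events(st)
    fx <- extract_fixations(st, ev)
    fx$trial <- tr
    fx_all[[tr]] <- fx
  }
  fixations <- do.call(rbind, fx_all)
  out <- structure(list(accuracy = accuracy_table(fixations, grid,
                                                  obj$screen),
                        precision = precision_table(fixations, grid,
                                                    obj$screen),
                        fixations = fixations,
                        n_trials = config$n_trials, config = config),
                   class = "accuracy_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "accuracy.csv")
    fp <- file.path(out_dir, "precision.csv")
    ff <- file.path(out_dir, "fixations.csv")
    utils::write.csv(out$accuracy, fa, row.names = FALSE)
    utils::write.csv(out$precision, fp, row.names = FALSE)
    utils::write.csv(fixations, ff, row.names = FALSE)
    jsonlite::write_json(run_manifest(config, c(fa, fp, ff)),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Accuracy/precision report over", x$n_trials, "trials of",
      nrow(x$accuracy), "targets\n")
  cat(sprintf("  |accuracy deviation| [deg]: x <= %.3f, y <= %.3f\n",
              max(abs(x$accuracy$dev_x_deg), na.rm = TRUE),
              max(abs(x$accuracy$dev_y_deg), na.rm = TRUE)))
  cat(sprintf("  precision SD [deg]: x %.3f-%.3f, y %.3f-%.3f\n",
              min(x$precision$sd_x_deg), max(x$precision$sd_x_deg),
              min(x$precision$sd_y_deg), max(x$precision$sd_y_deg)))
  invisible(x)
}

#' End-to-end brightness experiment and null-model tests
#'
#' Simulates the full null-model experiment (each participant one random
#' plan reused across the brightness conditions; condition changes the
#' measurement-noise realization but never the motion), detects and
#' filters saccades, fits per-participant-and-condition main sequences,
#' and runs the repeated-measures ANOVAs: fitted 10-degree peak velocity
#' with participants as subjects, and fixation pupil size with
#' participant x target fixations as subjects.
#'
#' @param config a [run_config()]
#' @param pupil also assemble the pupil matrix and its ANOVA
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @return an object of class `brightness_experiment`: `v10` matrix,
#'   `anova_v10`, `grand_v10`, per-condition `fits`, `pupil` matrix and
#'   `anova_pupil` (when requested), aggregated `exclusion_log`, `config`
#' @export
run_brightness_experiment <- function(config = run_config(), pupil = TRUE,
                                      out_dir = NULL) {
  obj <- config_objects(config)
  conds <- brightness_conditions()
  k <- nrow(conds)
  np <- config$n_participants
  nt <- config$n_saccades + 1L          # fixation targets per stream
  ev_all <- vector("list", np * k)
  pupil_mat <- if (pupil) matrix(NA_real_, np * nt, k,
                                 dimnames = list(NULL, conds$name))
  excl <- stats::setNames(numeric(5), c("transition", "fragment",
                                        "amplitude", "retained", "total"))
  for (p in seq_len(np)) {
    part <- simulate_participant(p, config$seed, config$n_saccades, conds,
                                 obj$screen, obj$camera, obj$motor,
                                 config$fixation_ms,
                                 config$condition_independent_noise,
                                 noise_sd_deg = config$noise_sd_deg,
                                 pupil_base_au = config$pupil_base_au,
                                 pupil_noise_au = config$pupil_noise_au)
    for (ci in seq_len(k)) {
      st <- part$streams[[ci]]
      ev <- detect_events(st)
      fl <- exclusion_filter(ev, config$amp_range)
      excl <- excl + stats::setNames(fl$log$count, fl$log$reason)
      ev_all[[(p - 1) * k + ci]] <- fl$events
      if (pupil) {
        fx <- suppressWarnings(extract_fixations(st, ev))
        if (nrow(fx) > 0) {
          ok <- fx$target_index <= nt
          pupil_mat[(p - 1) * nt + fx$target_index[ok], ci] <-
            fx$mean_pupil[ok]
        }
      }
    }
  }
  events <- do.call(rbind, ev_all)
  v10 <- per_condition_v10(events, conds$name)
  out <- list(v10 = v10$v10, anova_v10 = rm_anova(v10$v10),
              grand_v10 = v10$grand, fits = v10$fits,
              excluded_participants = v10$excluded,
              exclusion_log = excl, config = config)
  if (pupil) {
    pm <- pupil_mat[stats::complete.cases(pupil_mat), , drop = FALSE]
    out$pupil <- pm
    out$anova_pupil <- rm_anova(pm)
  }
  out <- structure(out, class = "brightness_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fv <- file.path(out_dir, "v10_matrix.csv")
    fe <- file.path(out_dir, "events.csv")
    utils::write.csv(as.data.frame(out$v10), fv, row.names = FALSE)
    write_events(events, fe)
    jsonlite::write_json(
      c(run_manifest(config, c(fv, fe)),
        list(anova_v10 = summary(out$anova_v10),
             grand_v10 = as.list(out$grand_v10),
             exclusions = as.list(excl))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.brightness_experiment <- function(x, ...) {
  cat("Brightness null experiment:", nrow(x$v10), "participants x",
      ncol(x$v10), "conditions\n")
  cat("  grand v10 [deg/s]: ",
      paste(sprintf("%s %.3f", names(x$grand_v10), x$grand_v10),
            collapse = ", "), "\n", sep = "")
  a <- x$anova_v10
  cat(sprintf("  v10 rm ANOVA: F(%d, %d) = %.4g, p = %.3f, partial eta^2 = %.4g\n",
              a$df_effect, a$df_error, a$F, a$p_uncorrected,
              a$partial_eta_sq))
  if (!is.null(x$anova_pupil)) {
    a <- x$anova_pupil
    cat(sprintf("  pupil rm ANOVA: F(%.3f, %.1f) = %.4g, p(HF) = %.3f\n",
                a$epsilon_hf * a$df_effect, a$epsilon_hf * a$df_error,
                a$F, a$p_hf))
  }
  cat("  exclusions: ",
      paste(names(x$exclusion_log), x$exclusion_log, sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
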