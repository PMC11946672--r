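#' Write / read a sample stream as TSV with a JSON sidecar
#'
#' The stream goes to a tab-separated file (`t_ms`, `x_px`, `y_px`,
#' `pupil_au`; positions and pupil rounded to 3 decimals) and the
#' simulation metadata (sampling rate, noise parameters, seeds, planned
#' targets, ground-truth move table, geometry) to `<path>.json`, enough
#' to regenerate or reinterpret the recording. `read_stream()` restores
#' the `sample_stream` with its attributes.
#'
#' @param stream a `sample_stream`
#' @param path output TSV path
#' @return `write_stream` returns `path` invisibly; `read_stream` returns
#'   the restored `sample_stream`
#' @export
write_stream <- function(stream, path) {
  out <- data.frame(t_ms = stream$t_ms,
                    x_px = round(stream$x_px, 3),
                    y_px = round(stream$y_px, 3),
                    pupil_au = round(stream$pupil_au, 3))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  scr <- attr(stream, "screen")
  cam <- attr(stream, "camera")
  meta <- list(fs_hz = attr(stream, "fs_hz"),
               noise_sd_deg = attr(stream, "noise_sd_deg"),
               pupil_base_au = attr(stream, "pupil_base_au"),
               pupil_noise_au = attr(stream, "pupil_noise_au"),
               seed = attr(stream, "seed"),
               has_transition = attr(stream, "has_transition"),
               fixation_ms = attr(stream, "fixation_ms"),
               condition = attr(stream, "condition"),
               participant = attr(stream, "participant"),
               targets_px = attr(stream, "targets_px"),
               truth = attr(stream, "truth"),
               screen = scr[c("width_mm", "height_mm", "width_px",
                              "height_px", "viewing_distance_mm")],
               camera = if (!is.null(cam))
                 list(offset_mm = cam$offset_mm,
                      eye_height_mm = cam$eye_height_mm))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  dat <- utils::read.delim(path, sep = "\t")
  need <- c("t_ms", "x_px", "y_px", "pupil_au")
  if (!all(need %in% names(dat)))
    stop("malformed stream header in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  for (cn in need)
    dat[[cn]] <- suppressWarnings(as.numeric(dat[[cn]]))
  bad <- which(!stats::complete.cases(dat[need]))
  if (length(bad) > 0)
    stop("malformed stream row at line ", bad[1] + 1L, " of ", path)
  dat$t_ms <- as.integer(dat$t_ms)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else list()
  scr <- if (!is.null(meta$screen)) do.call(screen_geometry, meta$screen)
         else screen_geometry()
  cam <- if (!is.null(meta$camera)) do.call(camera_geometry, meta$camera)
         else camera_geometry()
  structure(dat[need], class = c("sample_stream", "data.frame"),
            fs_hz = meta$fs_hz %||% 1000,
            noise_sd_deg = meta$noise_sd_deg,
            pupil_base_au = meta$pupil_base_au,
            pupil_noise_au = meta$pupil_noise_au,
            seed = meta$seed,
            has_transition = isTRUE(meta$has_transition),
            fixation_ms = meta$fixation_ms,
            condition = meta$condition,
            participant = meta$participant,
            targets_px = if (!is.null(meta$targets_px))
              as.matrix(meta$targets_px),
            truth = if (!is.null(meta$truth)) as.data.frame(meta$truth),
            screen = scr, camera = cam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read detected events as CSV
#'
#' Angle and velocity columns are rounded to 3 decimals.
#'
#' @param events a [detect_events()] result (or any event data.frame)
#' @param path CSV path
#' @export
write_events <- function(events, path) {
  ev <- as.data.frame(events)
  for (cn in intersect(c("amplitude_deg", "peak_velocity_dps",
                         "direction_deg"), names(ev)))
    ev[[cn]] <- round(ev[[cn]], 3)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  need <- c("onset_ms", "offset_ms", "amplitude_deg", "peak_velocity_dps")
  if (!all(need %in% names(ev)))
    stop("malformed events header in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  bad <- which(!stats::complete.cases(ev[c("onset_ms", "offset_ms")]))
  if (length(bad) > 0)
    stop("malformed events row at line ", bad[1] + 1L, " of ", path)
  ev
}

#' Export a stream in an ASC-like text dialect
#'
#' Writes one tab-separated sample line per stream sample — time, x, y,
#' pupil, the layout common gaze tools expect from converted tracker
#' recordings — preceded by `**`-prefixed comment lines. The number of
#' sample lines equals the stream length.
#'
#' @param stream a `sample_stream`
#' @param path output path
#' @export
write_asc <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("** CONVERTED FROM sample_stream",
               sprintf("** RATE %.2f", attr(stream, "fs_hz") %||% 1000)),
             con)
  writeLines(sprintf("%d\t%.1f\t%.1f\t%.1f", stream$t_ms, stream$x_px,
                     stream$y_px, stream$pupil_au), con)
  invisible(path)
}
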