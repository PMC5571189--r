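#' Write a membrane recording to disk
#'
#' The trace is written as a long-format CSV (`time_s`, `vm_mv`); events,
#' metadata, and ground-truth tables go to a JSON sidecar named
#' `<stem>_meta.json` next to it, so the pair round-trips losslessly through
#' [read_recording()].
#'
#' @param rec a `membrane_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "membrane_recording"))
  df <- data.frame(time_s = sprintf("%.8f", time_axis(rec)),
                   vm_mv = sprintf("%.10g", rec$vm))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate_hz = rec$sampling_rate_hz,
               duration_s = rec$duration_s,
               seed = rec$meta$seed,
               events = rec$events,
               transitions = rec$meta$transitions,
               evoked = rec$meta$evoked,
               input_resistance_mohm = rec$meta$input_resistance_mohm)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.json")
}

#' Read a membrane recording written by [write_recording()]
#'
#' @param path CSV path.
#' @return a `membrane_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  df <- utils::read.csv(path)
  for (col in c("time_s", "vm_mv"))
    if (is.null(df[[col]]))
      stop("read_recording: malformed file, missing column '", col, "'")
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("read_recording: missing metadata sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (fld in c("sampling_rate_hz", "duration_s"))
    if (is.null(meta[[fld]]))
      stop("read_recording: malformed sidecar, missing field '", fld, "'")
  steps <- diff(df$time_s)
  if (length(steps) && (max(steps) - min(steps)) > 1e-6)
    stop("read_recording: malformed file, time axis not uniform")
  ev <- meta$events
  if (is.null(ev) || !length(ev))
    ev <- data.frame(time_s = numeric(), kind = character())
  new_membrane_recording(df$vm_mv, meta$sampling_rate_hz, meta$duration_s,
    as.data.frame(ev),
    meta = list(seed = meta$seed,
                transitions = as.data.frame(meta$transitions),
                evoked = as.data.frame(meta$evoked),
                input_resistance_mohm = meta$input_resistance_mohm))
}

#' Write / read an event schedule as JSON
#'
#' @param events data.frame (`time_s`, `kind`).
#' @param path JSON path.
#' @return `write_event_schedule` returns `path` invisibly;
#'   `read_event_schedule` returns the event data.frame.
#' @export
write_event_schedule <- function(events, path) {
  stopifnot(all(c("time_s", "kind") %in% names(events)))
  jsonlite::write_json(events, path, digits = NA)
  invisible(path)
}

#' @rdname write_event_schedule
#' @export
read_event_schedule <- function(path) {
  ev <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(ev$time_s) || is.null(ev$kind))
    stop("read_event_schedule: malformed file, need fields time_s and kind")
  as.data.frame(ev)
}
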