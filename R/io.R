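#' Default channel schema
#'
#' Maps the force-sensor hardware axes (columns `fl*`/`fr*` of a signal CSV)
#' onto the anatomical body frame. The sensors are belt-mounted so that the
#' sensor x axis points along the walking direction (AP); the remaining axes
#' follow a right-handed frame with ML positive toward the patient's right
#' and SI positive upward. Both sensors are assumed to be expressed in this
#' common frame after mounting.
#'
#' @return named character vector mapping sensor axes to body axes.
#' @export
default_channel_schema <- function() {
  c(x = "AP", y = "ML", z = "SI")
}

meta_header <- function(meta) {
  if (is.null(meta)) return(character())
  paste0("# ", names(meta), ": ", vapply(meta, format, ""))
}

write_csv_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- meta_header(meta)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

check_uniform_time <- function(t, rel_tol = 1e-6) {
  if (length(t) < 2L) return(1)
  dt <- diff(t)
  dt0 <- stats::median(dt)
  bad <- which(abs(dt - dt0) > rel_tol * dt0)
  if (length(bad))
    stop(sprintf("non-uniform time column: step %d is %.9g s, expected %.9g s",
                 bad[1L], dt[bad[1L]], dt0), call. = FALSE)
  dt0
}

#' Read a session recording from CSV
#'
#' Accepts either a single CSV with columns
#' `t,ax,ay,az[,flx,fly,flz,frx,fry,frz]` (accel and force sharing one
#' clock) or a file stem for which `<stem>_accel.csv` and optionally
#' `<stem>_force.csv` exist (used when the two systems run at different
#' rates). Lines starting with `#` are metadata and ignored. Times are in
#' seconds and the time column must be uniform to a relative tolerance of
#' 1e-6; violations are rejected with the offending step index.
#'
#' @param path CSV file path or file stem.
#' @param schema sensor-axis to body-axis map, see [default_channel_schema()].
#' @param body_mass optional patient body mass (kg) to attach.
#' @return a [session_recording()].
#' @export
read_signals <- function(path, schema = default_channel_schema(),
                         body_mass = NA_real_) {
  if (file.exists(path)) {
    df <- utils::read.csv(path, comment.char = "#")
    need <- c("t", "ax", "ay", "az")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    dt <- check_uniform_time(df$t)
    fs <- 1 / dt
    accel <- list(x = signal_track(df$ax, fs, df$t[1L]),
                  y = signal_track(df$ay, fs, df$t[1L]),
                  z = signal_track(df$az, fs, df$t[1L]))
    fcols <- c("flx", "fly", "flz", "frx", "fry", "frz")
    if (any(fcols %in% names(df))) {
      miss <- setdiff(fcols, names(df))
      if (length(miss))
        stop(sprintf("incomplete force channels, missing: %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
      fl <- force_side_from_cols(df, "fl", fs, df$t[1L], schema)
      fr <- force_side_from_cols(df, "fr", fs, df$t[1L], schema)
      return(session_recording(accel, fl, fr, body_mass = body_mass))
    }
    return(session_recording(accel, body_mass = body_mass))
  }
  acc_path <- paste0(path, "_accel.csv")
  frc_path <- paste0(path, "_force.csv")
  if (!file.exists(acc_path))
    stop(sprintf("no such file: %s (nor %s)", path, acc_path), call. = FALSE)
  rec <- read_signals(acc_path, schema = schema, body_mass = body_mass)
  if (!file.exists(frc_path)) return(rec)
  df <- utils::read.csv(frc_path, comment.char = "#")
  need <- c("t", "flx", "fly", "flz", "frx", "fry", "frz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  dt <- check_uniform_time(df$t)
  fs <- 1 / dt
  session_recording(rec$accel,
                    force_side_from_cols(df, "fl", fs, df$t[1L], schema),
                    force_side_from_cols(df, "fr", fs, df$t[1L], schema),
                    body_mass = body_mass)
}

force_side_from_cols <- function(df, prefix, fs, t0, schema) {
  out <- list()
  for (ax in names(schema))
    out[[schema[[ax]]]] <- signal_track(df[[paste0(prefix, ax)]], fs, t0)
  out[c("ML", "AP", "SI")]
}

force_side_to_cols <- function(side, prefix, schema) {
  out <- list()
  for (ax in names(schema))
    out[[paste0(prefix, ax)]] <- side[[schema[[ax]]]]$samples
  out
}

#' Write a session recording to CSV
#'
#' Inverse of [read_signals()]: one CSV when accel and force share a
#' sampling rate (or force is absent), otherwise a `<stem>_accel.csv` /
#' `<stem>_force.csv` pair. The round trip reproduces the recording to
#' within 1e-9 per sample.
#'
#' @param rec a [session_recording()].
#' @param path output file (single-rate) or stem (dual-rate).
#' @param schema see [default_channel_schema()].
#' @param meta optional named list written as `# key: value` header lines.
#' @return invisibly, the path(s) written.
#' @export
write_signals <- function(rec, path, schema = default_channel_schema(),
                          meta = NULL) {
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  acc <- data.frame(t = fmt(track_times(rec$accel$x)),
                    ax = fmt(rec$accel$x$samples),
                    ay = fmt(rec$accel$y$samples),
                    az = fmt(rec$accel$z$samples))
  if (!has_force(rec)) {
    write_csv_with_meta(acc, path, meta)
    return(invisible(path))
  }
  same_rate <- isTRUE(all.equal(rec$accel$x$fs, rec$force_left$ML$fs)) &&
    length(rec$accel$x$samples) == length(rec$force_left$ML$samples) &&
    isTRUE(all.equal(rec$accel$x$t0, rec$force_left$ML$t0))
  fcols <- c(force_side_to_cols(rec$force_left, "fl", schema),
             force_side_to_cols(rec$force_right, "fr", schema))
  fcols <- lapply(fcols, fmt)
  if (same_rate) {
    write_csv_with_meta(cbind(acc, as.data.frame(fcols)), path, meta)
    return(invisible(path))
  }
  acc_path <- paste0(path, "_accel.csv")
  frc_path <- paste0(path, "_force.csv")
  write_csv_with_meta(acc, acc_path, meta)
  frc <- cbind(data.frame(t = fmt(track_times(rec$force_left$ML))),
               as.data.frame(fcols))
  write_csv_with_meta(frc, frc_path, meta)
  invisible(c(acc_path, frc_path))
}

#' Locate the synchronization peak in a force channel
#'
#' The two measurement systems are synchronized by pressing a switch against
#' one force sensor at the instant the accelerometer recording is triggered,
#' which leaves a sharp spike in that force channel. The sync instant is the
#' time of the maximum absolute value within an initial search window; after
#' alignment it becomes t = 0.
#'
#' @param force_track a [signal_track()] (N).
#' @param search_window_s length of the initial search window in seconds.
#' @param prominence_factor the peak must exceed this multiple of the
#'   track-wide median absolute value, else a "no sync peak" error is raised.
#' @return sync time in seconds (on the track's own clock).
#' @export
detect_sync_peak <- function(force_track, search_window_s,
                             prominence_factor = 5) {
  assert_that(search_window_s > 0, "search_window_s must be > 0")
  assert_that(force_track$t0 + search_window_s <= track_end(force_track) + 1e-9,
              "search window extends beyond track")
  idx <- track_window(force_track, force_track$t0,
                      force_track$t0 + search_window_s)
  absx <- abs(force_track$samples[idx])
  floor_v <- prominence_factor * stats::median(abs(force_track$samples))
  peak <- max(absx)
  if (peak <= floor_v || peak == 0)
    stop("no sync peak: maximum within the search window does not clear the prominence floor",
         call. = FALSE)
  track_times(force_track)[idx[which.max(absx)]]
}

#' Align force data to the synchronization peak and trim
#'
#' Shifts the force tracks so that the sync instant maps to t = 0 and drops
#' force samples recorded before it. The accelerometer clock is untouched
#' (its recording is triggered at the sync instant, so its t = 0 is already
#' aligned). Annotations logged on the force-system clock are shifted by the
#' same amount. Inter-sample spacing and event durations are preserved
#' exactly.
#'
#' @param rec a [session_recording()] with force channels.
#' @param sync_s sync time from [detect_sync_peak()].
#' @param annotations optional [assist_annotations()] on the pre-alignment
#'   force clock.
#' @return the aligned recording, or `list(recording, annotations)` when
#'   annotations are supplied.
#' @export
align_and_trim <- function(rec, sync_s, annotations = NULL) {
  assert_that(has_force(rec), "recording has no force channels to align")
  ref <- rec$force_left$ML
  assert_that(sync_s >= ref$t0 - 1e-9 && sync_s <= track_end(ref) + 1e-9,
              "sync time outside force track extent")
  shift_track <- function(tr) {
    tt <- track_times(tr) - sync_s
    keep <- which(tt >= -1e-9)
    signal_track(tr$samples[keep], tr$fs, t0 = tt[keep[1L]])
  }
  out <- session_recording(
    rec$accel,
    lapply(rec$force_left, shift_track),
    lapply(rec$force_right, shift_track),
    body_mass = rec$body_mass,
    walking_direction_axis = rec$walking_direction_axis)
  if (is.null(annotations)) return(out)
  ann <- assist_annotations(annotations$start_s - sync_s,
                            annotations$stop_s - sync_s,
                            annotations$location, annotations$sensors_hit)
  list(recording = out, annotations = ann)
}

#' Read / write assistance annotations
#'
#' CSV (`start_s,stop_s,location,sensors_hit`, `#` comments allowed) or a
#' JSON array of objects with the same keys; the format is inferred from the
#' file extension. Lists are returned sorted by `start_s`; intervals with
#' `stop_s <= start_s` are rejected with the offending row index.
#'
#' @param path file path (`.csv`, `.json`).
#' @return an [assist_annotations()] data frame.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (is.list(df) && !is.data.frame(df) && length(df) == 0L)
      df <- data.frame(start_s = numeric(), stop_s = numeric(),
                       location = character(), sensors_hit = character())
  } else {
    df <- utils::read.csv(path, comment.char = "#",
                          colClasses = c(start_s = "numeric", stop_s = "numeric",
                                         location = "character",
                                         sensors_hit = "character"))
  }
  if (nrow(df) == 0L) return(assist_annotations())
  assist_annotations(df$start_s, df$stop_s, df$location, df$sensors_hit)
}

#' @rdname read_annotations
#' @param annotations an [assist_annotations()] data frame.
#' @param meta optional named list of metadata (`# key: value` lines, CSV
#'   only).
#' @export
write_annotations <- function(annotations, path, meta = NULL) {
  df <- as.data.frame(annotations)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    write_csv_with_meta(df, path, meta)
  }
  invisible(path)
}
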