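#' A synchronized therapist-patient training session recording
#'
#' Bundles the 3-axis sacral accelerometer with the left/right pelvis force
#' sensors and patient metadata. The accelerometer and the force system may
#' run at different sampling rates; all downstream comparison is done in
#' seconds, never in samples. Force channels are kept in the anatomical body
#' frame (ML = medio-lateral, positive toward the patient's right; AP =
#' anterior-posterior, positive forward; SI = superior-inferior, positive up).
#'
#' @param accel named list of three [signal_track()]s, `x`, `y`, `z` (m/s^2),
#'   sharing sampling rate and length.
#' @param force_left,force_right `NULL` (accel-only session) or named lists
#'   of three [signal_track()]s, `ML`, `AP`, `SI` (N), all four sharing
#'   sampling rate and length.
#' @param body_mass patient body mass in kg, > 0.
#' @param walking_direction_axis label of the sensor axis aligned with the
#'   walking direction (the mounting convention of the force sensors).
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(accel, force_left = NULL, force_right = NULL,
                              body_mass = NA_real_,
                              walking_direction_axis = "x") {
  assert_that(is.list(accel) && all(c("x", "y", "z") %in% names(accel)),
              "accel must be a named list with tracks x, y, z")
  for (ax in c("x", "y", "z"))
    assert_that(inherits(accel[[ax]], "signal_track"),
                sprintf("accel$%s is not a signal_track", ax))
  assert_that(same_clock(accel$x, accel$y) && same_clock(accel$x, accel$z),
              "accelerometer tracks must share fs and length")
  has_force <- !is.null(force_left) || !is.null(force_right)
  if (has_force) {
    assert_that(!is.null(force_left) && !is.null(force_right),
                "force_left and force_right must both be present or both NULL")
    for (side in list(force_left, force_right)) {
      assert_that(is.list(side) && all(c("ML", "AP", "SI") %in% names(side)),
                  "force sides must be named lists with tracks ML, AP, SI")
      for (ax in c("ML", "AP", "SI"))
        assert_that(inherits(side[[ax]], "signal_track"),
                    "force channels must be signal_tracks")
    }
    ref <- force_left$ML
    for (tr in c(force_left, force_right))
      assert_that(same_clock(ref, tr), "force tracks must share fs and length")
  }
  if (!is.na(body_mass))
    assert_that(body_mass > 0, "body_mass must be > 0")
  structure(list(accel = accel, force_left = force_left,
                 force_right = force_right, body_mass = body_mass,
                 walking_direction_axis = walking_direction_axis),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> accel %d samples @ %g Hz%s, body mass %s kg\n",
    length(x$accel$x$samples), x$accel$x$fs,
    if (is.null(x$force_left)) ", no force channels"
    else sprintf("; force %d samples @ %g Hz",
                 length(x$force_left$ML$samples), x$force_left$ML$fs),
    format(x$body_mass)))
  invisible(x)
}

has_force <- function(rec) !is.null(rec$force_left)

#' Ground-truth assistance annotations
#'
#' One row per balance-assisting event: the interval over which the
#' therapist applied corrective force, where on the body contact was made,
#' and how many of the two pelvis force sensors were hit. Events not at the
#' iliac crest cannot hit the sensors, so `sensors_hit` must be `"none"`
#' exactly for those.
#'
#' @param start_s,stop_s event interval in seconds, `stop_s > start_s >= 0`.
#' @param location one of `"iliac_crest"`, `"trunk"`, `"shoulder"`, `"other"`.
#' @param sensors_hit one of `"both"`, `"one"`, `"none"`; defaults to
#'   `"both"` at the iliac crest and `"none"` elsewhere.
#' @return a `data.frame` with class `assist_annotations`, sorted by
#'   `start_s`.
#' @export
assist_annotations <- function(start_s = numeric(), stop_s = numeric(),
                               location = character(), sensors_hit = NULL) {
  n <- length(start_s)
  assert_that(length(stop_s) == n && length(location) == n,
              "start_s, stop_s and location must have equal length")
  location <- as.character(location)
  if (is.null(sensors_hit))
    sensors_hit <- ifelse(location == "iliac_crest", "both", "none")
  sensors_hit <- as.character(sensors_hit)
  assert_that(length(sensors_hit) == n, "sensors_hit has wrong length")
  bad_loc <- setdiff(unique(location),
                     c("iliac_crest", "trunk", "shoulder", "other"))
  assert_that(length(bad_loc) == 0L,
              paste("unknown location label(s):", paste(bad_loc, collapse = ", ")))
  bad_hit <- setdiff(unique(sensors_hit), c("both", "one", "none"))
  assert_that(length(bad_hit) == 0L,
              paste("unknown sensors_hit label(s):", paste(bad_hit, collapse = ", ")))
  if (n > 0) {
    bad <- which(!(stop_s > start_s & start_s >= 0))
    if (length(bad))
      stop(sprintf("invalid annotation interval at row %d (need stop_s > start_s >= 0)",
                   bad[1L]), call. = FALSE)
    mism <- which((sensors_hit == "none") != (location != "iliac_crest"))
    if (length(mism))
      stop(sprintf("row %d: sensors_hit must be 'none' iff location is not the iliac crest",
                   mism[1L]), call. = FALSE)
  }
  out <- data.frame(start_s = as.numeric(start_s), stop_s = as.numeric(stop_s),
                    location = location, sensors_hit = sensors_hit,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start_s, out$stop_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assist_annotations", "data.frame")
  out
}
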