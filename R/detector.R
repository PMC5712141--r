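#' Detector parameters
#'
#' `alpha` scales the Tukey fence height (threshold = Q3 + alpha * IQR) and
#' `delta_s` is the moving-average window width in seconds. Larger `alpha`
#' demands larger sustained deviations; larger `delta_s` demands that they
#' last longer.
#'
#' @param alpha threshold factor, >= 0.
#' @param delta_s moving-average window width in seconds, > 0.
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(alpha = 1.0, delta_s = 2.5) {
  assert_that(is.numeric(alpha) && length(alpha) == 1L && alpha >= 0,
              "alpha must be a single number >= 0")
  assert_that(is.numeric(delta_s) && length(delta_s) == 1L && delta_s > 0,
              "delta_s must be a single number > 0")
  structure(list(alpha = alpha, delta_s = delta_s), class = "detector_params")
}

#' Resultant (vector-norm) acceleration
#'
#' Per-sample Euclidean norm of the three accelerometer axes. Using the norm
#' makes the analysis independent of how the sensor was oriented on the
#' sacrum.
#'
#' @param ax,ay,az [signal_track()]s of equal sampling rate and length.
#' @return a [signal_track()] with the per-sample norm.
#' @export
resultant_acceleration <- function(ax, ay, az) {
  assert_that(same_clock(ax, ay) && same_clock(ax, az),
              "accelerometer tracks must share fs and length")
  track_with(ax, sqrt(ax$samples^2 + ay$samples^2 + az$samples^2))
}

#' Free acceleration (gravity removal)
#'
#' Subtracts the mean of the resultant from every sample, removing the
#' gravitational component and leaving the free acceleration. The output
#' mean is zero to within 1e-9.
#'
#' @param resultant a [signal_track()], typically from
#'   [resultant_acceleration()].
#' @return zero-mean [signal_track()].
#' @export
free_acceleration <- function(resultant) {
  track_with(resultant, resultant$samples - mean(resultant$samples))
}

#' Trim stationary lead-in and lead-out
#'
#' Removes the periods before the patient starts moving and after they stop,
#' leaving only movement data. With `manual = c(from, to)` exactly those
#' bounds are used. Otherwise the leading/trailing region where a centred
#' rolling standard deviation (window `sd_window_s`) stays below
#' `frac` times the whole-record standard deviation is dropped. Interior
#' samples are never removed.
#'
#' @param track a [signal_track()].
#' @param manual optional `c(from, to)` seconds.
#' @param sd_window_s rolling-SD window width in seconds.
#' @param frac activity floor as a fraction of the whole-record SD.
#' @return `list(track, kept = c(from, to))`.
#' @export
trim_stationary <- function(track, manual = NULL, sd_window_s = 1,
                            frac = 0.1) {
  tt <- track_times(track)
  if (!is.null(manual)) {
    assert_that(length(manual) == 2L && manual[2L] > manual[1L],
                "manual bounds must be c(from, to) with to > from")
    assert_that(manual[1L] >= track$t0 - 1e-9 &&
                  manual[2L] <= track_end(track) + 1e-9,
                "manual bounds outside track")
    idx <- track_window(track, manual[1L], manual[2L])
    return(list(track = signal_track(track$samples[idx], track$fs, tt[idx[1L]]),
                kept = c(tt[idx[1L]], tt[idx[length(idx)]])))
  }
  x <- track$samples
  n <- length(x)
  w <- max(2L, round(sd_window_s * track$fs))
  half <- w %/% 2L
  rsd <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::sd(x[lo:hi])
  }, 0)
  active <- rsd >= frac * stats::sd(x)
  if (!any(active))
    return(list(track = track, kept = c(track$t0, track_end(track))))
  lo <- which(active)[1L]
  hi <- which(active)[sum(active)]
  list(track = signal_track(x[lo:hi], track$fs, tt[lo]),
       kept = c(tt[lo], tt[hi]))
}

#' Centred moving average
#'
#' Window width is `round(delta_s * fs)` samples, forced odd by adding one
#' so the window is symmetric about the output sample. At the record ends
#' the window shrinks to what is available, so output length equals input
#' length.
#'
#' @param track a [signal_track()].
#' @param delta_s window width in seconds, > 0.
#' @return the smoothed [signal_track()].
#' @export
moving_average <- function(track, delta_s) {
  assert_that(delta_s > 0, "delta_s must be > 0")
  x <- track$samples
  n <- length(x)
  w <- max(1L, round(delta_s * track$fs))
  if (w %% 2L == 0L) w <- w + 1L
  assert_that(w <= n, "moving-average window longer than the record")
  half <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  track_with(track, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Tukey-fence threshold
#'
#' Quartiles of the (trimmed, pre-smoothing) free-acceleration resultant,
#' and the upper outlier fence `Q3 + alpha * IQR`.
#'
#' @param track a [signal_track()].
#' @param alpha fence factor, >= 0.
#' @param convention quantile convention, see [signal_quartiles()].
#' @return `list(threshold, q1, q3, iqr)`.
#' @export
tukey_threshold <- function(track, alpha, convention = "linear") {
  q <- signal_quartiles(track$samples, convention)
  list(threshold = unname(q["q3"] + alpha * q["iqr"]),
       q1 = unname(q["q1"]), q3 = unname(q["q3"]), iqr = unname(q["iqr"]))
}

# contiguous runs of a logical vector -> closed sample-index intervals
runs_to_intervals <- function(marked) {
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# sample-index runs -> time intervals; offset covers the last marked sample
indices_to_times <- function(runs, track) {
  tt <- track_times(track)
  data.frame(onset_s = tt[runs[, "start"]],
             offset_s = tt[runs[, "end"]] + 1 / track$fs)
}

#' Detect balance-assistance episodes from sacral acceleration
#'
#' The full prediction pipeline: resultant norm, gravity removal (mean over
#' the full record, before trimming), stationary-tail trimming, Tukey-fence
#' threshold from the trimmed pre-smoothing signal, centred moving average
#' of width `delta_s`, and marking of samples whose averaged value is
#' strictly above the threshold. Contiguous marked samples form one detected
#' interval.
#'
#' @param accel a [session_recording()] or a named list of `x`, `y`, `z`
#'   [signal_track()]s.
#' @param params a [detector_params()].
#' @param trim `"auto"` (default), `"none"`, or manual bounds `c(from, to)`
#'   in seconds, see [trim_stationary()].
#' @param quartiles_on `"raw"` (threshold quartiles from the unsmoothed
#'   trimmed signal, the default) or `"smoothed"`.
#' @param rectify if `TRUE`, smooth the absolute value of the free
#'   acceleration instead of the signed signal.
#' @param convention quantile convention, see [signal_quartiles()].
#' @return an object of class `detection_result`: list with `intervals`
#'   (data frame `onset_s`, `offset_s`), `threshold`, `quartiles`, `params`,
#'   `kept` (trim bounds) and the `smoothed` track.
#' @export
detect <- function(accel, params = detector_params(), trim = "auto",
                   quartiles_on = c("raw", "smoothed"), rectify = FALSE,
                   convention = "linear") {
  quartiles_on <- match.arg(quartiles_on)
  if (inherits(accel, "session_recording")) accel <- accel$accel
  res <- resultant_acceleration(accel$x, accel$y, accel$z)
  free <- free_acceleration(res)
  if (identical(trim, "none")) {
    trimmed <- list(track = free, kept = c(free$t0, track_end(free)))
  } else if (identical(trim, "auto")) {
    trimmed <- trim_stationary(free)
  } else {
    trimmed <- trim_stationary(free, manual = trim)
  }
  sig <- trimmed$track
  if (rectify) sig <- track_with(sig, abs(sig$samples))
  smoothed <- moving_average(sig, params$delta_s)
  qsrc <- if (quartiles_on == "raw") sig else smoothed
  thr <- tukey_threshold(qsrc, params$alpha, convention)
  marked <- smoothed$samples > thr$threshold
  runs <- runs_to_intervals(marked)
  intervals <- if (nrow(runs)) indices_to_times(runs, smoothed)
               else data.frame(onset_s = numeric(), offset_s = numeric())
  structure(list(intervals = intervals, threshold = thr$threshold,
                 quartiles = c(q1 = thr$q1, q3 = thr$q3, iqr = thr$iqr),
                 params = params, kept = trimmed$kept, smoothed = smoothed),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> %d interval(s), threshold %.4g (Q3 %.4g, IQR %.4g), alpha %.2f, delta %.2f s\n",
    nrow(x$intervals), x$threshold, x$quartiles["q3"], x$quartiles["iqr"],
    x$params$alpha, x$params$delta_s))
  invisible(x)
}
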