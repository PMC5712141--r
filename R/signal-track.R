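#' Uniformly sampled scalar signal
#'
#' The basic carrier for one channel of accelerometer (m/s^2) or force (N)
#' data. Sample `i` (1-based) is taken at time `t0 + (i - 1) / fs` seconds.
#'
#' @param samples numeric vector, length >= 1.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `signal_track`.
#' @examples
#' st <- signal_track(sin(seq(0, 2 * pi, length.out = 60)), fs = 60)
#' track_times(st)[1:3]
#' @export
signal_track <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  assert_that(length(samples) >= 1L, "signal_track: need at least one sample")
  assert_that(is.numeric(fs) && length(fs) == 1L && fs > 0,
              "signal_track: fs must be a single positive number")
  assert_that(is.numeric(t0) && length(t0) == 1L && is.finite(t0),
              "signal_track: t0 must be a single finite number")
  structure(list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
              length(x$samples), x$fs, x$t0, track_end(x)))
  invisible(x)
}

#' Sample times of a track
#' @param track a [signal_track()].
#' @return numeric vector of times in seconds.
#' @export
track_times <- function(track) {
  track$t0 + (seq_along(track$samples) - 1) / track$fs
}

#' Time of the last sample
#' @inheritParams track_times
#' @export
track_end <- function(track) {
  track$t0 + (length(track$samples) - 1) / track$fs
}

# indices of samples with time in [from, to] (closed, with fp tolerance)
track_window <- function(track, from, to) {
  eps <- 1e-9
  tt <- track_times(track)
  which(tt >= from - eps & tt <= to + eps)
}

# replace samples, keep clock
track_with <- function(track, samples) {
  signal_track(samples, fs = track$fs, t0 = track$t0)
}

same_clock <- function(a, b) {
  isTRUE(all.equal(a$fs, b$fs)) && length(a$samples) == length(b$samples)
}
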