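#' Remove static baseline offset
#'
#' Force sensors carry a mounting-dependent offset; it is estimated as the
#' mean over a static interval recorded before the patient starts moving and
#' subtracted from every sample.
#'
#' @param track a [signal_track()].
#' @param static_interval `c(from, to)` in seconds, inside the track and at
#'   least 0.1 s long.
#' @return the offset-corrected [signal_track()].
#' @export
remove_baseline <- function(track, static_interval) {
  assert_that(length(static_interval) == 2L &&
                static_interval[2L] > static_interval[1L],
              "static_interval must be c(from, to) with to > from")
  assert_that(static_interval[2L] - static_interval[1L] >= 0.1 - 1e-9,
              "static interval must be at least 0.1 s long")
  assert_that(static_interval[1L] >= track$t0 - 1e-9 &&
                static_interval[2L] <= track_end(track) + 1e-9,
              "static interval outside track")
  idx <- track_window(track, static_interval[1L], static_interval[2L])
  track_with(track, track$samples - mean(track$samples[idx]))
}

#' Net corrective force between the two hands
#'
#' With one sensor on each iliac crest, the net corrective force on the
#' patient is the difference between the left and the right sensor, computed
#' per body axis: `net(t) = left(t) - right(t)`. Positive ML means a push
#' toward the patient's right. When only one hand hits a sensor the
#' difference under- or over-shoots the true net force; this is a known
#' property of the setup and is not corrected.
#'
#' @param left,right named lists of `ML`, `AP`, `SI` [signal_track()]s in a
#'   common body frame, equal sampling rate and length.
#' @return named list of `ML`, `AP`, `SI` net-force tracks.
#' @export
resultant_force <- function(left, right) {
  out <- list()
  for (ax in c("ML", "AP", "SI")) {
    assert_that(same_clock(left[[ax]], right[[ax]]),
                sprintf("left/right %s tracks differ in fs or length", ax))
    out[[ax]] <- track_with(left[[ax]],
                            left[[ax]]$samples - right[[ax]]$samples)
  }
  out
}

#' Characterize one balance-assisting event
#'
#' Over the annotated interval: the peak force per axis is the maximum
#' absolute net force (reported irrespective of push direction), the
#' duration is the annotated `stop - start`, and the impulse is the
#' trapezoidal time integral of the rectified net ML force. Peaks are also
#' expressed in percent body weight using `g = 9.81` m/s^2. Events that did
#' not hit the force sensors (`sensors_hit == "none"`) carry no force
#' information and are returned with `available = FALSE` and `NA` metrics.
#'
#' @param net net-force tracks from [resultant_force()].
#' @param annotation one-row [assist_annotations()] (or a list with
#'   `start_s`, `stop_s`, `location`, `sensors_hit`).
#' @param body_mass patient body mass in kg, > 0.
#' @param gravity_mps2 gravitational acceleration for the %BW conversion.
#' @return one-row `data.frame`: `peak_ML_N`, `peak_AP_N`, `peak_SI_N`,
#'   `peak_ML_pct_bw`, `peak_AP_pct_bw`, `peak_SI_pct_bw`, `duration_s`,
#'   `impulse_Ns`, `location`, `sensors_hit`, `available`.
#' @export
event_metrics <- function(net, annotation, body_mass, gravity_mps2 = 9.81) {
  assert_that(is.numeric(body_mass) && body_mass > 0, "body_mass must be > 0")
  start <- annotation$start_s[1L]; stop <- annotation$stop_s[1L]
  loc <- annotation$location[1L];  hit <- annotation$sensors_hit[1L]
  base <- data.frame(peak_ML_N = NA_real_, peak_AP_N = NA_real_,
                     peak_SI_N = NA_real_, peak_ML_pct_bw = NA_real_,
                     peak_AP_pct_bw = NA_real_, peak_SI_pct_bw = NA_real_,
                     duration_s = stop - start, impulse_Ns = NA_real_,
                     location = loc, sensors_hit = hit, available = FALSE,
                     stringsAsFactors = FALSE)
  if (identical(hit, "none")) return(base)
  ref <- net$ML
  assert_that(start >= ref$t0 - 1e-9 && stop <= track_end(ref) + 1e-9,
              "annotation interval outside net-force extent")
  idx <- track_window(ref, start, stop)
  assert_that(length(idx) >= 2L, "annotation spans fewer than two force samples")
  tt <- track_times(ref)[idx]
  for (ax in c("ML", "AP", "SI")) {
    pk <- max(abs(net[[ax]]$samples[idx]))
    base[[paste0("peak_", ax, "_N")]] <- pk
    base[[paste0("peak_", ax, "_pct_bw")]] <-
      pk / (body_mass * gravity_mps2) * 100
  }
  base$impulse_Ns <- trapz(tt, abs(net$ML$samples[idx]))
  base$available <- TRUE
  base
}

#' Force characteristics for every event of a session
#'
#' Convenience pipeline: low-pass filter all six force channels, optionally
#' remove the static baseline, form the two-hand net force, and compute
#' [event_metrics()] for every annotation.
#'
#' @param rec a [session_recording()] with force channels.
#' @param annotations an [assist_annotations()] data frame.
#' @param filter_order,filter_cutoff_hz Butterworth settings, see
#'   [lowpass()].
#' @param static_interval optional `c(from, to)` for [remove_baseline()].
#' @param gravity_mps2 see [event_metrics()].
#' @return data frame with one row per annotation (in `start_s` order).
#' @export
session_force_metrics <- function(rec, annotations, filter_order = 2,
                                  filter_cutoff_hz = 5,
                                  static_interval = NULL,
                                  gravity_mps2 = 9.81) {
  assert_that(has_force(rec), "recording has no force channels")
  prep <- function(side) {
    lapply(side, function(tr) {
      tr <- lowpass(tr, filter_order, filter_cutoff_hz)
      if (!is.null(static_interval)) tr <- remove_baseline(tr, static_interval)
      tr
    })
  }
  net <- resultant_force(prep(rec$force_left), prep(rec$force_right))
  rows <- lapply(seq_len(nrow(annotations)), function(i)
    event_metrics(net, annotations[i, , drop = FALSE], rec$body_mass,
                  gravity_mps2))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- event_metrics(net, assist_annotations(0, 1, "iliac_crest"),
                         rec$body_mass)[0, ]
  rownames(out) <- NULL
  out
}

#' Cohort summary of force characteristics
#'
#' Median and IQR across patients of per-patient mean event metrics.
#' Patients without any sensor-captured event (all metrics unavailable) are
#' excluded.
#'
#' @param per_patient data frame of per-patient mean metrics; numeric
#'   columns are summarized.
#' @return data frame with one row per metric: `median`, `iqr`, `n`.
#' @export
summarize_cohort <- function(per_patient) {
  num <- vapply(per_patient, is.numeric, TRUE)
  assert_that(any(num), "no numeric metric columns to summarize")
  keep <- stats::complete.cases(per_patient[, num, drop = FALSE])
  df <- per_patient[keep, num, drop = FALSE]
  assert_that(nrow(df) >= 1L, "no patients with available metrics")
  out <- data.frame(metric = names(df),
                    median = vapply(df, stats::median, 0),
                    iqr = vapply(df, function(x)
                      unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7))), 0),
                    n = nrow(df), row.names = NULL, stringsAsFactors = FALSE)
  out
}
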