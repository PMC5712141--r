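#' Simulator configuration
#'
#' Describes one synthetic therapist-patient training session. Defaults are
#' anchored to the clinical setting the package targets: a 60 Hz sacral
#' accelerometer, a 100 Hz force acquisition system, slow hemiparetic gait
#' (step frequency 1.6 Hz, gait-related acceleration amplitude 1.5 m/s^2,
#' broadband sensor/soft-tissue noise SD 0.3 m/s^2), sparse assistance
#' episodes (log-normal duration, median 1.1 s) with a sustained
#' acceleration boost of 3x the noise SD, and two-hand corrective force
#' pulses whose net medio-lateral peak is log-normal with median 15.9 N
#' (about 2% body weight at 84 kg). Event locations follow the observed
#' split: 48% hit both pelvis sensors, 30% one sensor, 22% another body
#' location (trunk/shoulder, no force captured).
#'
#' @param duration_s session length in seconds.
#' @param accel_fs,force_fs sampling rates in Hz.
#' @param step_freq_hz gait step frequency.
#' @param gait_amp_mps2 amplitude of the gait acceleration fundamental.
#' @param noise_sd_mps2 white-noise SD per accelerometer axis.
#' @param n_events number of assistance episodes.
#' @param min_separation_s minimum gap between episode starts.
#' @param event_duration_median_s,event_duration_sdlog log-normal episode
#'   duration parameters (sdlog 0.4 reproduces an IQR of ~0.6 s about the
#'   1.1 s median).
#' @param event_boost_mps2 sustained acceleration boost during an episode;
#'   default `3 * noise_sd_mps2`.
#' @param force_peak_median_n,force_peak_sdlog log-normal net ML peak-force
#'   parameters (sdlog 0.5 reproduces an IQR of ~11 N about the 15.9 N
#'   median).
#' @param secondary_hand_fraction fraction of the leading hand's force
#'   carried by the trailing hand in two-hand events.
#' @param p_location probabilities for `both` sensors, `one` sensor, `other`
#'   body location; must sum to 1.
#' @param body_mass_kg patient body mass.
#' @param seed integer seed; identical config + seed gives bitwise-identical
#'   sessions.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 120, accel_fs = 60, force_fs = 100,
                       step_freq_hz = 1.6, gait_amp_mps2 = 1.5,
                       noise_sd_mps2 = 0.3, n_events = 5,
                       min_separation_s = 5,
                       event_duration_median_s = 1.1,
                       event_duration_sdlog = 0.4,
                       event_boost_mps2 = 3 * noise_sd_mps2,
                       force_peak_median_n = 15.9, force_peak_sdlog = 0.5,
                       secondary_hand_fraction = 0.3,
                       p_location = c(both = 0.48, one = 0.30, other = 0.22),
                       body_mass_kg = 84, seed = 1L) {
  p_location <- unlist(p_location)  # accept list input from JSON/YAML configs
  cfg <- as.list(environment())
  assert_that(duration_s > 0 && accel_fs > 0 && force_fs > 0 &&
                step_freq_hz > 0, "rates and duration must be > 0")
  assert_that(n_events >= 0 && min_separation_s >= 0, "invalid event layout")
  assert_that(n_events * min_separation_s < duration_s,
              "min_separation_s * n_events must be < duration_s")
  assert_that(abs(sum(p_location) - 1) < 1e-9 &&
                all(c("both", "one", "other") %in% names(p_location)),
              "p_location must be named (both, one, other) and sum to 1")
  assert_that(body_mass_kg > 0, "body_mass_kg must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

GRAVITY_MPS2 <- 9.81

# place n event starts uniformly in [margin, horizon] with pairwise gaps
# >= sep (stick-breaking construction, exact and retry-free)
place_events <- function(n, margin, horizon, sep) {
  if (n == 0L) return(numeric())
  free <- (horizon - margin) - (n - 1) * sep
  if (free <= 0)
    stop("could not place events with the requested separation", call. = FALSE)
  u <- sort(stats::runif(n, 0, free))
  margin + u + (seq_len(n) - 1) * sep
}

raised_cosine <- function(t, start, duration) {
  u <- (t - start) / duration
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Simulate one training session
#'
#' Generates the sacral acceleration and the two pelvis force-sensor
#' channel sets for a session with known assistance episodes, plus the
#' ground-truth annotations. The accelerometer sees gravity on its z (SI)
#' axis, gait oscillation mostly on the horizontal (AP/ML) axes with a small
#' vertical harmonic, white noise on all axes, and during each episode a
#' sustained boost on the SI axis (a loss of balance produces a sustained,
#' not oscillatory, deviation; the therapist's correction pushes the pelvis
#' upward and sideways). Iliac-crest events additionally carry a
#' raised-cosine force pulse: the leading (left) hand exerts the larger
#' force, the trailing hand a `secondary_hand_fraction` share, and the net
#' left-minus-right ML peak equals the drawn peak. Events at other body
#' locations produce the acceleration boost but no force.
#'
#' @param cfg a [sim_config()].
#' @return `list(recording = session_recording, annotations =
#'   assist_annotations)`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    na <- round(cfg$duration_s * cfg$accel_fs)
    ta <- (seq_len(na) - 1) / cfg$accel_fs
    f <- cfg$step_freq_hz
    A <- cfg$gait_amp_mps2
    gait_x <- A * sin(2 * pi * f * ta) + 0.3 * A * sin(4 * pi * f * ta + 0.8)
    gait_y <- 0.4 * A * sin(pi * f * ta + 0.3)         # ML sway at stride rate
    gait_z <- 0.15 * A * sin(4 * pi * f * ta + 1.1)    # small vertical bounce
    ax <- gait_x + stats::rnorm(na, 0, cfg$noise_sd_mps2)
    ay <- gait_y + stats::rnorm(na, 0, cfg$noise_sd_mps2)
    az <- GRAVITY_MPS2 + gait_z + stats::rnorm(na, 0, cfg$noise_sd_mps2)

    durations <- stats::rlnorm(cfg$n_events,
                               meanlog = log(cfg$event_duration_median_s),
                               sdlog = cfg$event_duration_sdlog)
    margin <- 1
    horizon <- cfg$duration_s - margin -
      (if (cfg$n_events) max(durations) else 0)
    assert_that(cfg$n_events == 0L || horizon > margin,
                "session too short for the requested events")
    starts <- place_events(cfg$n_events, margin, horizon,
                           cfg$min_separation_s)
    stops <- starts + durations

    cats <- if (cfg$n_events)
      sample(c("both", "one", "other"), cfg$n_events, replace = TRUE,
             prob = cfg$p_location[c("both", "one", "other")])
    else character()
    location <- ifelse(cats == "other",
                       sample(c("trunk", "shoulder"), max(cfg$n_events, 1),
                              replace = TRUE)[seq_along(cats)],
                       "iliac_crest")
    sensors_hit <- ifelse(cats == "other", "none", cats)

    for (i in seq_along(starts)) {
      idx <- ta >= starts[i] & ta <= stops[i]
      az[idx] <- az[idx] + cfg$event_boost_mps2
    }

    nf <- round(cfg$duration_s * cfg$force_fs)
    tf <- (seq_len(nf) - 1) / cfg$force_fs
    zero <- numeric(nf)
    fl <- list(ML = zero, AP = zero, SI = zero)
    fr <- list(ML = zero, AP = zero, SI = zero)
    peaks <- stats::rlnorm(max(cfg$n_events, 0),
                           meanlog = log(cfg$force_peak_median_n),
                           sdlog = cfg$force_peak_sdlog)
    for (i in seq_along(starts)) {
      if (sensors_hit[i] == "none") next
      shape <- raised_cosine(tf, starts[i], durations[i])
      if (sensors_hit[i] == "both") {
        lead <- peaks[i] / (1 - cfg$secondary_hand_fraction)
        fl$ML <- fl$ML + lead * shape
        fr$ML <- fr$ML + cfg$secondary_hand_fraction * lead * shape
      } else {
        fl$ML <- fl$ML + peaks[i] * shape
      }
      # small AP/SI components (~10% of the ML force)
      fl$AP <- fl$AP + 0.12 * peaks[i] * shape
      fl$SI <- fl$SI + 0.12 * peaks[i] * shape
    }

    accel <- list(x = signal_track(ax, cfg$accel_fs),
                  y = signal_track(ay, cfg$accel_fs),
                  z = signal_track(az, cfg$accel_fs))
    mk <- function(side) lapply(side, signal_track, fs = cfg$force_fs, t0 = 0)
    rec <- session_recording(accel, mk(fl), mk(fr),
                             body_mass = cfg$body_mass_kg)
    ann <- if (cfg$n_events)
      assist_annotations(starts, stops, location, sensors_hit)
    else assist_annotations()
    list(recording = rec, annotations = ann,
         truth = list(durations = durations, peaks = peaks,
                      sensors_hit = sensors_hit))
  })
}

#' Simulate a patient cohort
#'
#' One session per patient with per-patient derived seeds and body masses
#' drawn around 84 kg (SD 7.2 kg).
#'
#' @param n_patients number of patients, >= 1.
#' @param cfg template [sim_config()]; per-patient seed and body mass are
#'   overridden.
#' @param seed cohort-level seed.
#' @param mass_mean_kg,mass_sd_kg body-mass distribution.
#' @return named list (`"1"`, `"2"`, ...) of [simulate_session()] outputs.
#' @export
simulate_cohort <- function(n_patients = 8, cfg = sim_config(), seed = 1L,
                            mass_mean_kg = 84, mass_sd_kg = 7.2) {
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  masses <- with_seed(seed,
                      pmax(40, stats::rnorm(n_patients, mass_mean_kg, mass_sd_kg)))
  out <- lapply(seq_len(n_patients), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- (as.integer(seed) %% 1000000L) * 1000L + i
    cfg_i$body_mass_kg <- masses[i]
    simulate_session(cfg_i)
  })
  names(out) <- as.character(seq_len(n_patients))
  out
}
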