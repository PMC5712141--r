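# Fixtures are built in code; nothing binary is stored.

const_track <- function(value, n = 100, fs = 60, t0 = 0) {
  signal_track(rep(value, n), fs = fs, t0 = t0)
}

# a session whose accel and force share one clock (single-CSV layout)
single_rate_session <- function(fs = 50, n = 200, seed = 11) {
  set.seed(seed)
  tr <- function() signal_track(rnorm(n), fs = fs)
  side <- function() list(ML = tr(), AP = tr(), SI = tr())
  session_recording(list(x = tr(), y = tr(), z = tr()), side(), side(),
                    body_mass = 80)
}

# random proper rotation matrix
random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_accel <- function(accel, R) {
  M <- rbind(accel$x$samples, accel$y$samples, accel$z$samples)
  M2 <- R %*% M
  list(x = track_with(accel$x, M2[1, ]),
       y = track_with(accel$y, M2[2, ]),
       z = track_with(accel$z, M2[3, ]))
}

# an easily separable synthetic session: few long, strong episodes
separable_config <- function(seed = 5, duration_s = 60) {
  sim_config(duration_s = duration_s, n_events = 3, min_separation_s = 12,
             event_duration_median_s = 2, event_duration_sdlog = 0,
             event_boost_mps2 = 8, seed = seed)
}

max_abs_diff_rec <- function(a, b) {
  d <- max(abs(a$accel$x$samples - b$accel$x$samples),
           abs(a$accel$y$samples - b$accel$y$samples),
           abs(a$accel$z$samples - b$accel$z$samples))
  if (!is.null(a$force_left))
    for (ax in c("ML", "AP", "SI"))
      d <- max(d,
               abs(a$force_left[[ax]]$samples - b$force_left[[ax]]$samples),
               abs(a$force_right[[ax]]$samples - b$force_right[[ax]]$samples))
  d
}
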