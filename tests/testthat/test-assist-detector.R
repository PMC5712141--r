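test_that("resultant acceleration is the per-sample norm and rotation invariant", {
  n <- 50
  r <- resultant_acceleration(const_track(3, n), const_track(4, n),
                              const_track(0, n))
  expect_equal(r$samples, rep(5, n))
  z <- resultant_acceleration(const_track(0, n), const_track(0, n),
                              const_track(0, n))
  expect_equal(z$samples, rep(0, n))

  set.seed(4)
  accel <- list(x = signal_track(rnorm(200), 60),
                y = signal_track(rnorm(200), 60),
                z = signal_track(rnorm(200) + 9.81, 60))
  base <- resultant_acceleration(accel$x, accel$y, accel$z)$samples
  for (k in 1:5) {
    rot <- rotate_accel(accel, random_rotation())
    expect_equal(resultant_acceleration(rot$x, rot$y, rot$z)$samples, base,
                 tolerance = 1e-9)
  }
  expect_error(resultant_acceleration(const_track(1, 50), const_track(1, 40),
                                      const_track(1, 50)),
               "share fs and length")
})

test_that("free acceleration removes the mean exactly", {
  expect_equal(free_acceleration(const_track(9.81, 60))$samples, rep(0, 60))
  expect_equal(free_acceleration(signal_track(c(1, 3), 60))$samples, c(-1, 1))
  set.seed(5)
  x <- rnorm(500); x <- x - mean(x)
  out <- free_acceleration(signal_track(x, 60))
  expect_equal(out$samples, x, tolerance = 1e-12)
  expect_lt(abs(mean(out$samples)), 1e-9)
})

test_that("stationary tails are trimmed, interiors kept", {
  fs <- 60
  set.seed(6)
  quiet <- function(s) rnorm(s * fs, 0, 0.005)
  walk <- 1.5 * sin(2 * pi * 1.6 * (0:(20 * fs - 1)) / fs) + rnorm(20 * fs, 0, 0.3)
  tr <- signal_track(c(quiet(5), walk, quiet(5)), fs)
  out <- trim_stationary(tr)
  expect_lt(abs(out$kept[1] - 5), 1.0)
  expect_lt(abs(out$kept[2] - 25), 1.0)

  # no stationary tails -> identity
  tr2 <- signal_track(walk, fs)
  out2 <- trim_stationary(tr2)
  expect_equal(out2$track$samples, walk)

  # manual bounds select exactly the requested samples
  out3 <- trim_stationary(tr, manual = c(2, 10))
  expect_equal(out3$kept, c(2, 10))
  expect_equal(length(out3$track$samples), 8 * fs + 1)
  expect_error(trim_stationary(tr, manual = c(-5, 10)), "outside track")
})

test_that("moving average: centred shrink-edge window, exact small cases", {
  expect_equal(moving_average(const_track(4.2, 100), 0.5)$samples, rep(4.2, 100))

  tr <- signal_track(c(0, 0, 3, 0, 0), fs = 1)
  expect_equal(moving_average(tr, 3)$samples[3], 1.0)

  set.seed(8)
  x <- rnorm(40)
  expect_equal(moving_average(signal_track(x, 60), 1 / 60)$samples, x)

  expect_error(moving_average(signal_track(x, 60), 10), "longer than the record")

  # equals the naive loop oracle for random widths
  for (k in 1:10) {
    n <- sample(50:400, 1)
    fs <- sample(c(20, 60, 100), 1)
    x <- rnorm(n)
    delta <- runif(1, 1.5 / fs, (n - 2) / fs)
    w <- max(1, round(delta * fs)); if (w %% 2 == 0) w <- w + 1
    if (w > n) next
    expect_equal(moving_average(signal_track(x, fs), delta)$samples,
                 oracle_moving_average(x, w), tolerance = 1e-12)
  }
})

test_that("Tukey fence threshold from signal quartiles", {
  tr <- signal_track(seq(0, 100), fs = 1)
  th <- tukey_threshold(tr, alpha = 1)
  expect_equal(th$q3, 75)
  expect_equal(th$iqr, 50)
  expect_equal(th$threshold, 125)
  expect_equal(tukey_threshold(tr, alpha = 0)$threshold, 75)

  cn <- tukey_threshold(const_track(2.5, 50), alpha = 3)
  expect_equal(cn$iqr, 0)
  expect_equal(cn$threshold, 2.5)

  # quantiles equal an independent interpolation oracle
  set.seed(10)
  for (k in 1:10) {
    x <- rnorm(sample(20:500, 1))
    q <- signal_quartiles(x)
    expect_equal(unname(q["q1"]), oracle_quantile(x, 0.25), tolerance = 1e-12)
    expect_equal(unname(q["q3"]), oracle_quantile(x, 0.75), tolerance = 1e-12)
  }
})

test_that("detect equals the naive brute-force pipeline on random records", {
  set.seed(12)
  for (k in 1:30) {
    n <- sample(200:1500, 1)
    fs <- sample(c(20, 60), 1)
    t <- (0:(n - 1)) / fs
    boost <- numeric(n)
    if (runif(1) < 0.7) {  # sometimes inject a detectable episode
      at <- sample(seq_len(n - 50), 1)
      boost[at:(at + sample(10:50, 1))] <- runif(1, 1, 6)
    }
    ax <- 1.2 * sin(2 * pi * 1.5 * t) + rnorm(n, 0, 0.3)
    ay <- rnorm(n, 0, 0.3)
    az <- 9.81 + boost + rnorm(n, 0, 0.3)
    alpha <- runif(1, 0, 3)
    delta <- runif(1, 2 / fs, min(3, (n - 2) / fs))
    got <- detect(list(x = signal_track(ax, fs), y = signal_track(ay, fs),
                       z = signal_track(az, fs)),
                  detector_params(alpha, delta), trim = "none")
    ref <- oracle_detect(ax, ay, az, fs, alpha, delta)
    expect_equal(nrow(got$intervals), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$intervals$onset_s, ref$onset_s, tolerance = 1e-9)
      expect_equal(got$intervals$offset_s, ref$offset_s, tolerance = 1e-9)
    }
  }
})

test_that("detection is monotone in alpha and silent on constant records", {
  s <- simulate_session(sim_config(duration_s = 60, n_events = 3,
                                   min_separation_s = 10,
                                   event_boost_mps2 = 3, seed = 21))
  marked <- sapply(seq(0, 3, by = 0.25), function(a) {
    d <- detect(s$recording, detector_params(a, 1.0), trim = "none")
    sum(d$smoothed$samples > d$threshold)
  })
  expect_true(all(diff(marked) <= 0))

  flat <- list(x = const_track(1, 400), y = const_track(2, 400),
               z = const_track(9.6, 400))
  for (a in c(0.1, 1, 3))
    expect_equal(nrow(detect(flat, detector_params(a, 1.0),
                             trim = "none")$intervals), 0)
})

test_that("detect is invariant to fixed rotations of the sensor axes", {
  s <- simulate_session(sim_config(duration_s = 40, n_events = 3,
                                   min_separation_s = 8,
                                   event_boost_mps2 = 5, seed = 13))
  base <- detect(s$recording, detector_params(1, 1), trim = "none")
  set.seed(14)
  for (k in 1:5) {
    rot <- rotate_accel(s$recording$accel, random_rotation())
    d <- detect(rot, detector_params(1, 1), trim = "none")
    expect_equal(d$intervals, base$intervals, tolerance = 1e-9)
    expect_equal(d$threshold, base$threshold, tolerance = 1e-9)
  }
})

test_that("short isolated spikes are averaged away by wide windows", {
  fs <- 10
  set.seed(15)
  x <- rnorm(600, 0, 1)
  x[300] <- x[300] + 5  # single-sample spike
  accel <- list(x = signal_track(numeric(600), fs),
                y = signal_track(numeric(600), fs),
                z = signal_track(9.81 + x, fs))
  spike_t <- 299 / fs
  covers_spike <- function(d) {
    any(d$intervals$onset_s <= spike_t & d$intervals$offset_s >= spike_t)
  }
  # one-sample window: the spike is an outlier
  d_narrow <- detect(accel, detector_params(1, 1 / fs), trim = "none")
  expect_true(covers_spike(d_narrow))
  # 1.5 s window: the spike does not last long enough
  d_wide <- detect(accel, detector_params(1, 1.5), trim = "none")
  expect_false(covers_spike(d_wide))
})
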