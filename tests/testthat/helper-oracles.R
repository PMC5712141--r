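# Independent brute-force oracles (naive loops, own quantile interpolation).
# These deliberately share no code with the package internals.

oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 2 > n) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

oracle_moving_average <- function(x, w) {
  n <- length(x)
  half <- (w - 1) / 2
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, 0)
}

# naive reimplementation of the whole detector (no trimming)
oracle_detect <- function(ax, ay, az, fs, alpha, delta_s) {
  r <- sqrt(ax^2 + ay^2 + az^2)
  f <- r - mean(r)
  w <- max(1, round(delta_s * fs))
  if (w %% 2 == 0) w <- w + 1
  sm <- oracle_moving_average(f, w)
  q1 <- oracle_quantile(f, 0.25)
  q3 <- oracle_quantile(f, 0.75)
  thr <- q3 + alpha * (q3 - q1)
  marked <- sm > thr
  onsets <- c(); offsets <- c()
  inside <- FALSE
  for (i in seq_along(marked)) {
    if (marked[i] && !inside) { onsets <- c(onsets, i); inside <- TRUE }
    if (!marked[i] && inside) { offsets <- c(offsets, i - 1); inside <- FALSE }
  }
  if (inside) offsets <- c(offsets, length(marked))
  data.frame(onset_s = (onsets - 1) / fs,
             offset_s = (offsets - 1) / fs + 1 / fs)
}

# per-sample peak / trapezoid oracle for event metrics
oracle_event_peak_impulse <- function(t, y, start, stop) {
  idx <- which(t >= start - 1e-9 & t <= stop + 1e-9)
  peak <- 0; imp <- 0
  for (i in idx) peak <- max(peak, abs(y[i]))
  for (k in seq_len(length(idx) - 1)) {
    i <- idx[k]; j <- idx[k + 1]
    imp <- imp + (t[j] - t[i]) * (abs(y[i]) + abs(y[j])) / 2
  }
  list(peak = peak, impulse = imp)
}
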