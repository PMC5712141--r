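# Butterworth low-pass design and zero-phase filtering.
#
# The dedicated DSP packages are not part of this stack, so the small amount
# of filter machinery needed (bilinear-transform Butterworth design, a
# direct-form-II-transposed filter loop, steady-state initial conditions and
# odd-extension forward-backward filtering) is implemented here. The
# forward-backward path is numerically equivalent to scipy.signal.filtfilt
# with its default padding.

polynomial_from_roots <- function(r) {
  co <- 1
  for (ri in r) co <- c(co, 0) - c(0, ri * co)
  co
}

#' Butterworth low-pass coefficients
#'
#' @param order filter order (>= 1).
#' @param cutoff_hz -3 dB cutoff frequency in Hz, must be below Nyquist.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` (digital, `a[1]=1`).
#' @export
butter_lowpass <- function(order, cutoff_hz, fs) {
  assert_that(order >= 1, "order must be >= 1")
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2))
    stop("cutoff frequency must lie in (0, fs/2)", call. = FALSE)
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  p_analog <- warped * exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * order)))
  p_digital <- (2 * fs + p_analog) / (2 * fs - p_analog)
  gain <- Re(warped^order / prod(2 * fs - p_analog))
  b <- gain * choose(order, 0:order)          # zeros at z = -1
  a <- Re(polynomial_from_roots(p_digital))
  list(b = b, a = a / a[1L])
}

# |H(e^{i 2 pi f / fs})| for coefficient sets b, a
filter_gain <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  num <- vapply(w, function(wi) sum(b * exp(-1i * wi * (seq_along(b) - 1))), 0i)
  den <- vapply(w, function(wi) sum(a * exp(-1i * wi * (seq_along(a) - 1))), 0i)
  Mod(num / den)
}

# direct form II transposed single-pass filter
filter_df2t <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1L]; a <- a / a[1L]
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (n > 2L)
      for (j in 1:(n - 2L)) z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial filter state for a unit step input
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1L]; a <- a / a[1L]
  ns <- n - 1L
  if (ns == 1L) {
    A <- matrix(-a[2L], 1L, 1L)
  } else {
    A <- rbind(-a[2:n], cbind(diag(1, ns - 1L), rep(0, ns - 1L)))
  }
  B <- b[2:n] - a[2:n] * b[1L]
  solve(diag(ns) - t(A), B)
}

# zero-phase forward-backward filtering with odd extension at both ends
filtfilt_fb <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  padlen <- 3L * nfilt
  n <- length(x)
  assert_that(n > padlen,
              sprintf("signal too short for zero-phase filtering (need > %d samples)", padlen))
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- filter_df2t(b, a, ext, zi * ext[1L])
  y <- rev(filter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Force channels are low-pass filtered before event characterization to
#' remove sensor noise above the band of manual corrections (defaults:
#' 2nd order, 5 Hz). The filter is applied forward and backward so event
#' timing is not lagged; the effective amplitude response is the square of
#' the single-pass Butterworth response.
#'
#' @param track a [signal_track()].
#' @param order filter order of the single pass.
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @return the filtered [signal_track()].
#' @export
lowpass <- function(track, order = 2, cutoff_hz = 5) {
  co <- butter_lowpass(order, cutoff_hz, track$fs)
  track_with(track, filtfilt_fb(co$b, co$a, track$samples))
}
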