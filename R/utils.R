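#' Round half away from zero
#'
#' Commercial rounding used by the reporting layer (R's `round()` rounds
#' half to even). Reported PPV/TPR percentages and table summaries use this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

#' Quartiles of a signal
#'
#' @param x numeric vector.
#' @param convention `"linear"` (interpolation between closest ranks,
#'   R quantile type 7, the default) or `"hinges"` (Tukey's hinges).
#' @return named vector `c(q1, q3, iqr)`.
#' @export
signal_quartiles <- function(x, convention = c("linear", "hinges")) {
  convention <- match.arg(convention)
  if (convention == "linear") {
    q <- stats::quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    f <- stats::fivenum(x)
    q <- f[c(2L, 4L)]
  }
  c(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}

# trapezoidal integral of y over abscissa t
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

# internal: stop unless cond
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
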