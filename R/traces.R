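#' Build a current trace
#'
#' A trace is the atomic signal object of the package: a uniformly sampled
#' whole-cell or patch current, stored as a tibble with a `time` column in
#' seconds and a `current` column in pA.  The sign convention is
#' physiological for inward chloride flux at negative holding potentials:
#' inward currents are negative.
#'
#' @param current Numeric vector of current samples (pA, inward negative).
#' @param rate Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return A tibble with columns `time` (s) and `current` (pA).
#' @examples
#' tr <- new_trace(rnorm(1000, sd = 2), rate = 10000)
#' trace_rate(tr)
#' @export
new_trace <- function(current, rate, t0 = 0) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    abort("`rate` must be a single positive number (Hz).")
  if (length(current) < 2)
    abort("a trace needs at least 2 samples.")
  if (!all(is.finite(current)))
    abort("`current` must be finite throughout.")
  tibble::tibble(
    time = t0 + (seq_along(current) - 1) / rate,
    current = as.numeric(current)
  )
}

#' Sampling rate of a trace
#'
#' Inferred from the median spacing of the `time` column; errors if the
#' spacing is not uniform to within 1 ppm.
#'
#' @param trace A trace tibble (`time`, `current`).
#' @return Sampling rate in Hz.
#' @export
trace_rate <- function(trace) {
  check_trace(trace)
  dt <- diff(trace$time)
  d0 <- median(dt)
  if (any(abs(dt - d0) > 1e-6 * d0))
    abort("trace is not uniformly sampled.")
  1 / d0
}

check_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time", "current") %in% names(trace)))
    abort("expected a trace: a data frame with `time` and `current` columns.")
  if (nrow(trace) < 2) abort("a trace needs at least 2 samples.")
  invisible(trace)
}

# Analogue Bessel low-pass prototype: poles are the roots of the reverse
# Bessel polynomial theta_n(s), rescaled so |H(j)| = 1/sqrt(2) at 1 rad/s
# (the amplifier's -3 dB convention).  Coefficients of theta_n from the
# closed form a_k = (2n-k)! / (2^(n-k) k! (n-k)!).
bessel_analog_poles <- function(n) {
  k <- 0:n
  lg <- lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) - lgamma(n - k + 1)
  coefs <- exp(lg)                       # ascending powers of s
  p <- polyroot(coefs)
  gain <- abs(prod(-p))                  # DC gain 1 for H(s) = gain / theta_n(s)
  mag2 <- function(w) (gain / abs(prod(1i * w - p)))^2
  w3 <- uniroot(function(w) mag2(w) - 0.5, c(1e-3, 10), tol = 1e-12)$root
  p / w3
}

#' Low-pass Bessel filter
#'
#' Applies an n-pole low-pass Bessel filter to a trace, mirroring the
#' analogue filtering stage of a patch-clamp amplifier.  The analogue
#' prototype (reverse-Bessel-polynomial poles, -3 dB magnitude
#' normalisation at the cutoff) is discretised by the bilinear transform
#' with frequency pre-warping at the cutoff, and applied either causally
#' (single pass, as acquisition hardware does) or, for offline feature
#' extraction, as a zero-phase forward-backward pass.
#'
#' @param trace A trace tibble.
#' @param cutoff Cutoff frequency in Hz (-3 dB point); must be below the
#'   Nyquist frequency.
#' @param poles Filter order, 4 or 8.
#' @param zero_phase If `TRUE`, filter forward and backward
#'   (`signal::filtfilt`) so no phase delay is introduced.
#' @return A new trace tibble, same length and rate; DC gain is exactly 1.
#' @examples
#' tr <- new_trace(rnorm(2000), rate = 20000)
#' smooth <- bessel_filter(tr, cutoff = 2000, poles = 8)
#' @export
bessel_filter <- function(trace, cutoff, poles = 4, zero_phase = FALSE) {
  check_trace(trace)
  rate <- trace_rate(trace)
  if (!poles %in% c(4, 8)) abort("`poles` must be 4 or 8.")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= rate / 2)
    abort(sprintf("invalid filter: cutoff must lie in (0, %.6g) Hz for this trace.", rate / 2))
  ba <- bessel_digital(cutoff, poles, rate)
  # filter relative to the first sample so the filter starts in steady
  # state (no spurious step response at the trace edge)
  x0 <- trace$current[1]
  xc <- trace$current - x0
  y <- x0 + if (zero_phase) {
    signal::filtfilt(signal::Arma(b = ba$b, a = ba$a), xc)
  } else {
    as.numeric(signal::filter(signal::Arma(b = ba$b, a = ba$a), xc))
  }
  tibble::tibble(time = trace$time, current = y)
}

# bilinear transform with pre-warp: analogue pole p -> (2fs + p) / (2fs - p),
# n zeros at z = -1, gain fixed for unit DC response.
bessel_digital <- function(cutoff, poles, rate) {
  warp <- 2 * rate * tan(pi * cutoff / rate)
  p <- bessel_analog_poles(poles) * warp
  fs2 <- 2 * rate
  pz <- (fs2 + p) / (fs2 - p)
  b <- Re(poly_from_roots(rep(-1 + 0i, poles)))
  a <- Re(poly_from_roots(pz))
  b <- b * sum(a) / sum(b)               # H(z = 1) = 1 exactly
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (rt in r) coefs <- c(coefs, 0) - c(0, coefs * rt)
  coefs
}

# analogue magnitude response of the package's Bessel prototype at
# normalised frequency w (cutoff = 1); used for response checks.
bessel_analog_gain <- function(w, poles) {
  p <- bessel_analog_poles(poles)
  gain <- abs(prod(-p))
  vapply(w, function(wi) gain / abs(prod(1i * wi - p)), numeric(1))
}

#' Subtract a baseline estimated over a time window
#'
#' Subtracts the mean current over `window` (a length-2 numeric, seconds)
#' from the whole trace, so that the windowed mean of the result is zero.
#'
#' @param trace A trace tibble.
#' @param window Numeric length-2: start and end of the baseline window (s).
#' @return The baseline-subtracted trace.
#' @export
subtract_baseline <- function(trace, window) {
  check_trace(trace)
  if (length(window) != 2 || window[2] <= window[1])
    abort("`window` must be c(start, end) with end > start.")
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(sel)) abort("baseline window contains no samples.")
  dplyr::mutate(trace, current = .data$current - mean(.data$current[sel]))
}
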