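#' Canonical event template
#'
#' A difference-of-exponentials event shape used by the scaled-template
#' detector, negative-going to match inward synaptic currents.
#'
#' @param rise_ms 20-80%-scale rise time constant, ms.
#' @param decay_ms Decay time constant, ms; must exceed `rise_ms`.
#' @param length_ms Template length, ms; defaults to 2 decay constants.
#'   Longer windows average more noise but mask events that fall within
#'   another event's window (at spontaneous rates of ~1 Hz a 5-decay
#'   window already loses ~7% of events to masking), so the default stays
#'   short.
#' @return An object of class `event_template`.
#' @export
event_template <- function(rise_ms = 0.8, decay_ms = 15,
                           length_ms = 2 * decay_ms) {
  if (rise_ms >= decay_ms) abort("template rise must be faster than decay.")
  if (length_ms < decay_ms + 5 * rise_ms)
    abort("template length must cover the rise and at least one decay constant.")
  structure(list(rise_ms = rise_ms, decay_ms = decay_ms,
                 length_ms = length_ms), class = "event_template")
}

template_wave <- function(template, rate) {
  t <- seq(0, template$length_ms / 1000, by = 1 / rate)
  w <- -(exp(-t / (template$decay_ms / 1000)) -
           exp(-t / (template$rise_ms / 1000)))
  w / max(abs(w))
}

# rolling dot product of x against a window w via FFT convolution;
# value j corresponds to alignment of w at x[j..j+L-1]
roll_dot <- function(x, w) {
  n <- length(x); L <- length(w)
  m <- nextn(n + L - 1, 2)
  fx <- fft(c(x, numeric(m - n)))
  fw <- fft(c(rev(w), numeric(m - L)))
  full <- Re(fft(fx * fw, inverse = TRUE)) / m
  full[L:n]
}

#' Detect synaptic events by scaled-template matching
#'
#' Slides the template along the trace; at every offset the template is fit
#' by optimal scale and offset (linear least squares), and the detection
#' statistic is the fitted scale divided by the residual standard error of
#' the fit, `scale / sqrt(SSE/(L-1))` — the scaled-template criterion of
#' sliding optimally-scaled-template detection.  Local maxima of the
#' statistic above `threshold`, separated by at least one template rise
#' time, are reported as events; each event's peak is the extremum of the
#' trace over the template span, measured from the locally fitted
#' baseline.
#'
#' Because the template is decay-dominated, the criterion forms a plateau
#' over each event's decay; candidates must therefore also show a genuine
#' rising phase: the steepest inward slope (2 kHz-filtered) near the
#' candidate onset must exceed `min_rise_frac` of the candidate amplitude
#' per ms.  A decay shoulder deepens at most at `1/tau_decay` of its local
#' amplitude per ms (~0.07/ms for a 15 ms decay), while even a slow 3 ms
#' rise deepens at ~0.2/ms, so the default separates the two cleanly and
#' lets summated events a few ms apart both be reported.
#'
#' @param trace A baseline-subtracted trace tibble.
#' @param template An [event_template()].
#' @param threshold Detection threshold on the criterion; default 4.
#' @param min_rise_frac Minimum onset slope as a fraction of the event
#'   amplitude per ms; default 0.2.
#' @return An event tibble: `event`, `onset`, `t_peak`, `amplitude` (pA,
#'   negative), `criterion`.
#' @export
detect_events <- function(trace, template, threshold = 4,
                          min_rise_frac = 0.2) {
  check_trace(trace)
  if (threshold <= 0) abort("`threshold` must be positive.")
  rate <- trace_rate(trace)
  w <- template_wave(template, rate)
  L <- length(w)
  x <- trace$current
  n <- length(x)
  if (L >= n) abort("template is longer than the trace.")

  sw <- sum(w); sww <- sum(w * w)
  den <- sww - sw^2 / L                 # sum((w - mean(w))^2)
  csx <- cumsum(c(0, x)); csx2 <- cumsum(c(0, x^2))
  noff <- n - L + 1
  sy <- csx[(L + 1):(n + 1)] - csx[1:noff]
  sy2 <- csx2[(L + 1):(n + 1)] - csx2[1:noff]
  sxy <- roll_dot(x, w)
  scale <- (sxy - sw * sy / L) / den
  sse <- pmax(sy2 - sy^2 / L - scale^2 * den, 0)
  se <- sqrt(sse / (L - 1))
  crit <- ifelse(se > 0, scale / se, 0)

  min_sep <- max(1L, round(template$rise_ms / 1000 * rate))
  peaks <- local_maxima(crit, threshold, min_sep)
  dy <- slope_trace(trace, rate)              # pA/ms, 2 kHz-filtered
  # summated events a few ms apart produce one criterion maximum only;
  # steep-slope points with a supra-threshold criterion are added as
  # candidates so each rise in a summated burst is examined
  steep_cand <- local_maxima(-dy, 0, min_sep)
  steep_cand <- steep_cand[steep_cand <= length(crit)]
  steep_cand <- steep_cand[crit[steep_cand] > threshold]
  if (length(peaks))
    steep_cand <- steep_cand[vapply(steep_cand, function(s)
      min(abs(s - peaks)) >= 2 * min_sep, logical(1))]
  peaks <- sort(unique(c(peaks, steep_cand)))
  # two nearby candidates belong to distinct events only if the current
  # relaxes (a peak, slope returning above the noise floor) somewhere
  # between them; candidates within one monotone rise are duplicates —
  # keep the strongest.  A fine slope window resolves the brief
  # relaxation between closely summated events.
  if (length(peaks) > 1) {
    dy_fine <- slope_trace(trace, rate, window_ms = 0.6)
    relax_thr <- 3 * mad(dy_fine, na.rm = TRUE)
    ord <- peaks[order(crit[peaks], decreasing = TRUE)]
    kept <- integer()
    for (j in ord) {
      dup <- FALSE
      for (k in kept) {
        if (abs(k - j) <= peak_span_of(template, rate) &&
            max(dy_fine[min(j, k):max(j, k)]) < relax_thr) {
          dup <- TRUE; break
        }
      }
      if (!dup) kept <- c(kept, j)
    }
    peaks <- sort(kept)
  }
  if (!length(peaks))
    return(tibble::tibble(event = integer(), onset = numeric(),
                          t_peak = numeric(), amplitude = numeric(),
                          criterion = numeric()))
  rise_span <- round((3 * template$rise_ms + 1) / 1000 * rate)
  # peak search stops shortly after the template's own time-to-peak so a
  # deeper overlapping neighbour does not capture the peak
  tpk <- template_peak_ms(template)
  peak_span <- peak_span_of(template, rate)
  base_w <- max(2L, round(0.002 * rate))
  next_onset <- c(peaks[-1] - 1L, n)
  rows <- lapply(seq_along(peaks), function(kk) {
    j <- peaks[kk]
    # reported amplitude is measured from the local pre-onset baseline
    # (exact on clean data, and the right reference for summated events);
    # the rise-slope gate instead uses the template-fit offset, which
    # keeps the full remaining depth of a decay plateau in the amplitude
    # and so rejects plateau candidates whose slopes are only noise
    offset_fit <- (sy[j] - scale[j] * sw) / L
    base <- if (j > base_w) mean(x[(j - base_w):(j - 1)]) else offset_fit
    # the peak search ends at the next candidate's onset so a summated
    # neighbour cannot capture this event's peak, but always covers the
    # template's own rise-to-peak (nearer candidates are duplicates that
    # the peak-level dedup resolves)
    floor_end <- j + round(tpk / 1000 * rate)
    idx <- j:max(min(j + 2L, n), min(n, max(floor_end,
                                            min(j + peak_span,
                                                next_onset[kk]))))
    rise_idx <- j:min(n, j + rise_span)
    pk_rel <- which.min(x[idx])
    steep <- -min(dy[rise_idx])
    tibble::tibble(onset = trace$time[j], t_peak = trace$time[idx[pk_rel]],
                   amplitude = x[idx[pk_rel]] - base,
                   amp_gate = x[idx[pk_rel]] - offset_fit,
                   criterion = crit[j], steep = steep)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$t_peak)
  out <- dplyr::filter(out, .data$steep >=
                         min_rise_frac * pmax(abs(.data$amp_gate),
                                              abs(.data$amplitude)))
  out$steep <- NULL
  out$amp_gate <- NULL
  if (!nrow(out))
    return(tibble::tibble(event = integer(), onset = numeric(),
                          t_peak = numeric(), amplitude = numeric(),
                          criterion = numeric()))
  # duplicate criterion maxima inside one event resolve to the same trace
  # extremum; keep the strongest
  out <- dplyr::slice_max(dplyr::group_by(out, .data$t_peak),
                          .data$criterion, n = 1, with_ties = FALSE)
  out <- dplyr::arrange(dplyr::ungroup(out), .data$t_peak)
  dplyr::mutate(out, event = dplyr::row_number(), .before = 1)
}

template_peak_ms <- function(template) {
  log(template$decay_ms / template$rise_ms) /
    (1 / template$rise_ms - 1 / template$decay_ms)
}

peak_span_of <- function(template, rate) {
  round((template_peak_ms(template) + 2) / 1000 * rate)
}

# local slope in pA/ms: rolling linear-regression slope over a short
# centred window on a 2 kHz-filtered copy — a per-sample derivative is far
# too noisy under channel-gating flicker to gate detections on
slope_trace <- function(trace, rate, window_ms = 2) {
  co <- min(2000, 0.4 * rate)
  filt <- bessel_filter(trace, cutoff = co, poles = 8, zero_phase = TRUE)
  L <- max(5L, round(window_ms / 1000 * rate))
  tc <- (seq_len(L) - (L + 1) / 2) / rate
  k <- tc / sum(tc^2)                 # regression weights
  sl <- roll_dot(filt$current, k) / 1000   # pA/ms at window start
  shift <- floor(L / 2)
  c(rep(sl[1], shift), sl, rep(sl[length(sl)], L - 1 - shift))[1:nrow(trace)]
}

# strict local maxima of v above `thr`, thinned greedily strongest-first
# to a minimum separation; every survivor is still a candidate only — the
# rise-slope gate downstream removes decay-plateau maxima that have no
# rising phase of their own
local_maxima <- function(v, thr, min_sep) {
  n <- length(v)
  cand <- which(v > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] >= v[cand + 1]]
  if (!length(cand)) return(integer())
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer()
  for (j in cand)
    if (!length(keep) || all(abs(keep - j) >= min_sep)) keep <- c(keep, j)
  sort(keep)
}
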