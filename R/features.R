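#' Flag events with clean rising and decay phases
#'
#' Reproduces the event-selection rules used to gate amplitude and kinetic
#' analyses: `clean_rise` requires no inflection (sign reversal of the
#' low-pass-filtered derivative beyond the noise floor) between the 10% and
#' 90% rise points; `clean_decay` additionally requires no secondary peak
#' — no re-deepening of the current beyond the noise floor — during the
#' decay back to 10% of the peak.  Mean-amplitude statistics should use
#' `clean_rise` events only, kinetic fits and fluctuation analysis
#' `clean_decay` events only; all-event analyses (rise rates, interevent
#' intervals, cumulative distributions) ignore both flags.
#'
#' @param events Event tibble from [detect_events()].
#' @param trace The trace the events were detected on.
#' @param filter_khz Cutoff (kHz) of the 8-pole Bessel filter applied
#'   before differentiation; default 2.
#' @param noise_k Multiples of the baseline noise SD treated as a real
#'   excursion; default 3.
#' @return The event tibble with logical columns `clean_rise`,
#'   `clean_decay`.
#' @export
flag_selection <- function(events, trace, filter_khz = 2, noise_k = 3) {
  check_trace(trace)
  rate <- trace_rate(trace)
  filt <- bessel_filter(trace, cutoff = filter_khz * 1000, poles = 8,
                        zero_phase = TRUE)
  y <- filt$current
  noise_sd <- mad(diff(y)) / sqrt(2)
  n <- length(y)
  flags <- purrr::map_dfr(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    i_on <- max(1L, round((ev$onset - trace$time[1]) * rate) + 1L)
    i_pk <- round((ev$t_peak - trace$time[1]) * rate) + 1L
    # the decay is inspected all the way to 10% of the peak (bounded at
    # 150 ms): a following summated event is exactly what must clear the
    # flag
    i_max <- min(n, i_pk + round(0.15 * rate))
    cr <- clean_rise_one(y, i_on, i_pk, ev$amplitude, noise_sd, noise_k)
    cd <- cr && clean_decay_one(y, i_pk, i_max, ev$amplitude,
                                noise_sd, noise_k)
    tibble::tibble(clean_rise = cr, clean_decay = cd)
  })
  dplyr::bind_cols(events, flags)
}

# rising phase between the 10% and 90% crossings must deepen monotonically
# (filtered derivative never reverses by more than the noise floor)
clean_rise_one <- function(y, i_on, i_pk, amplitude, noise_sd, noise_k) {
  if (i_pk - i_on < 3) return(TRUE)
  seg <- y[i_on:i_pk]
  base <- seg[1]
  depth <- amplitude            # negative
  i10 <- which(seg - base <= 0.1 * depth)[1]
  i90 <- which(seg - base <= 0.9 * depth)[1]
  if (is.na(i10) || is.na(i90) || i90 - i10 < 2) return(TRUE)
  d <- diff(seg[i10:i90])
  # inward rise: derivative should stay negative; a positive excursion
  # beyond noise marks an inflection/notch
  !any(d > noise_k * noise_sd * sqrt(2))
}

# decay back to 10% of peak must not re-deepen into a secondary peak: the
# current may not drop below the shallowest level it has already reached
# by more than the larger of the noise floor and a fraction of the peak
# (channel-gating flicker scales with the event, unlike a summated event)
clean_decay_one <- function(y, i_pk, i_max, amplitude, noise_sd, noise_k,
                            redeepen_frac = 0.25) {
  if (i_max - i_pk < 3) return(TRUE)
  seg <- y[i_pk:i_max]
  rel <- seg - seg[1] + amplitude      # current relative to local baseline
  stop_at <- which(rel >= 0.1 * amplitude)[1]   # decayed to 10% of peak
  if (!is.na(stop_at) && stop_at >= 3) seg <- seg[1:stop_at]
  if (length(seg) < 3) return(TRUE)
  run_min <- cummax(seg)         # shallowest level reached so far
  lim <- max(noise_k * noise_sd, redeepen_frac * abs(amplitude))
  !any(run_min - seg > lim)
}

#' Extract the per-event feature set
#'
#' Computes, for every event, the features used downstream: peak amplitude
#' (baseline-subtracted, pA); 10-90%, 20-80% and 30-70% rise times (ms,
#' threshold crossings located by linear interpolation); maximum rise
#' slope (pA/ms, measured on an 8-pole 2 kHz Bessel-filtered copy) and the
#' same normalized to the peak (1/ms); mean 20-80% rise slope normalized
#' to the peak (1/ms); interevent interval (s) and instantaneous frequency
#' (1/IEI, Hz); the burst window (shortest interval containing three
#' consecutive events including this one, s) and the coefficient of
#' variation of the intervals inside that window.  Events truncated by the
#' trace edge get missing features.
#'
#' @param events Flagged event tibble ([flag_selection()]).
#' @param trace The source trace at full sampling rate.
#' @param filter_khz Cutoff (kHz) for the slope filter; default 2.
#' @return The event tibble with all feature columns
#'   (see `event_table_columns()`).
#' @export
extract_features <- function(events, trace, filter_khz = 2) {
  check_trace(trace)
  rate <- trace_rate(trace)
  if (!nrow(events)) {
    cols <- setdiff(event_table_columns(), names(events))
    for (cl in cols) events[[cl]] <- numeric()
    return(events)
  }
  filt <- bessel_filter(trace, cutoff = filter_khz * 1000, poles = 8,
                        zero_phase = TRUE)
  dy <- c(NA, diff(filt$current)) * rate / 1000   # pA/ms
  n <- nrow(trace)

  per_event <- purrr::map_dfr(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    i_on <- round((ev$onset - trace$time[1]) * rate) + 1L
    i_pk <- round((ev$t_peak - trace$time[1]) * rate) + 1L
    i_end <- min(n, i_pk + ceiling(0.1 * rate))
    if (i_on < 1 || i_pk >= n || i_pk <= i_on) {
      return(tibble::tibble(rise_10_90 = NA_real_, rise_20_80 = NA_real_,
                            rise_30_70 = NA_real_, max_rise_slope = NA_real_,
                            max_rise_slope_norm = NA_real_,
                            rise_slope_norm = NA_real_))
    }
    seg <- trace$current[i_on:i_pk] - (trace$current[i_pk] - ev$amplitude)
    rt <- rise_times(seg, ev$amplitude, rate)
    mx <- -min(dy[i_on:i_pk], na.rm = TRUE)       # steepest inward slope, pA/ms
    tibble::tibble(
      rise_10_90 = rt[["r1090"]], rise_20_80 = rt[["r2080"]],
      rise_30_70 = rt[["r3070"]],
      max_rise_slope = mx,
      max_rise_slope_norm = mx / abs(ev$amplitude),
      rise_slope_norm = 0.6 / rt[["r2080"]]
    )
  })

  iei <- c(NA_real_, diff(events$t_peak))
  bw <- burst_windows(events$t_peak)
  out <- dplyr::bind_cols(events, per_event)
  out$iei <- iei
  out$inst_freq <- 1 / iei
  out$burst_window <- bw$window
  out$burst_cv <- bw$cv
  out
}

# fractional-threshold rise times (ms) by linear interpolation on the
# baseline-aligned rising segment; amplitude is negative
rise_times <- function(seg, amplitude, rate) {
  cross <- function(frac) {
    thr <- frac * amplitude
    j <- which(seg <= thr)[1]
    if (is.na(j)) return(NA_real_)
    if (j == 1) return(0)
    j - 1 + (thr - seg[j - 1]) / (seg[j] - seg[j - 1])
  }
  tms <- vapply(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), cross, numeric(1))
  dtms <- 1000 / rate
  c(r1090 = (tms[6] - tms[1]) * dtms,
    r2080 = (tms[5] - tms[2]) * dtms,
    r3070 = (tms[4] - tms[3]) * dtms)
}

# shortest window spanning three consecutive events that include event k,
# plus the CV of the two intervals inside the chosen triplet
burst_windows <- function(t_peak) {
  n <- length(t_peak)
  if (n < 3)
    return(list(window = rep(NA_real_, n), cv = rep(NA_real_, n)))
  win <- cv <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    starts <- max(1, k - 2):min(k, n - 2)
    spans <- t_peak[starts + 2] - t_peak[starts]
    j <- starts[which.min(spans)]
    win[k] <- t_peak[j + 2] - t_peak[j]
    ints <- diff(t_peak[j:(j + 2)])
    cv[k] <- sd(ints) / mean(ints)
  }
  list(window = win, cv = cv)
}
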