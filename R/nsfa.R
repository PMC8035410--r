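#' Peak-scaled variance-mean pairs over the decay
#'
#' For each peak-aligned event the mean waveform is scaled to the event's
#' own peak and subtracted over the decay; the across-event variance of
#' the residuals at each time point, paired with the mean current there,
#' forms the variance-mean relation that the parabola fit consumes.  Peak
#' scaling removes pure amplitude (multiplicative) variability, so the
#' remaining fluctuations reflect stochastic channel gating plus baseline
#' noise.
#'
#' @param aligned Output of [average_waveform()] with `align = "peak"`
#'   (uses `matrix`, `mean`, `peak_index`), restricted to clean-decay
#'   events.
#' @param window_frac Decay analysis window: from the peak until the mean
#'   current has relaxed to this fraction of its peak (default 0.1).
#' @param skip_ms Time after the peak excluded from the returned pairs
#'   (default 1 ms): the per-event scale factor pins the residuals near
#'   zero at the peak itself, so the first moments of the decay carry an
#'   artificial variance deficit that would bias the parabola fit.
#' @param min_events Minimum number of events required (default 25).
#' @return A tibble with columns `time`, `mean_current`, `variance`.
#' @export
peak_scaled_variance <- function(aligned, window_frac = 0.1, skip_ms = 1,
                                 min_events = 25) {
  M <- aligned$matrix
  if (nrow(M) < min_events)
    abort(sprintf("insufficient events for fluctuation analysis: %d < %d.",
                  nrow(M), min_events))
  pk <- aligned$peak_index
  mwave <- aligned$mean$current
  mpeak <- mwave[pk]
  rel <- mwave / mpeak
  stop_at <- which(seq_along(rel) > pk & rel <= window_frac)[1]
  if (is.na(stop_at)) stop_at <- length(mwave)
  win <- pk:stop_at
  # per-event scale from a short window about the peak rather than the
  # single noisy peak sample; cuts the spurious variance the scale factor
  # would otherwise re-inject along the decay
  rate <- 1 / diff(aligned$mean$time[1:2])
  hw <- max(1L, round(0.0005 * rate))
  pwin <- max(1, pk - hw):min(length(mwave), pk + hw)
  scales <- rowMeans(M[, pwin, drop = FALSE]) / mean(mwave[pwin])
  resid <- M[, win, drop = FALSE] - outer(scales, mwave[win])
  out <- tibble::tibble(
    time = aligned$mean$time[win],
    mean_current = colMeans(M[, win, drop = FALSE]),
    variance = apply(resid, 2, var)
  )
  out[out$time >= aligned$mean$time[pk] + skip_ms / 1000, ]
}

#' Fit the variance-mean parabola
#'
#' Bins the (mean current, variance) pairs into equal-count bins along the
#' mean current and fits `sigma^2 = i*I - I^2/N + var_b` by ordinary least
#' squares on the basis (I, I^2, 1).  The unitary current is the linear
#' coefficient, the receptor number the negative reciprocal of the
#' quadratic coefficient, and the intercept the baseline variance.  A
#' non-negative quadratic coefficient (no downward curvature on the
#' binomial scale) is an error: the data carry no channel-count
#' information.
#'
#' @param pairs Tibble with `mean_current` and `variance` (from
#'   [peak_scaled_variance()]), or any data frame with those columns.
#' @param n_bins Number of equal-count bins; default 50.  If fewer pairs
#'   than bins, pairs are used unbinned.
#' @return An object of class `nsfa_result`: `i` (pA), `n_channels`,
#'   `var_baseline` (pA^2), `binned` tibble, `r_squared`, `n_pairs`.
#' @examples
#' I <- seq(-1, -60, length.out = 200)
#' df <- data.frame(mean_current = I, variance = -2 * I - I^2 / 50)
#' parabola_fit(df)
#' @export
parabola_fit <- function(pairs, n_bins = 50) {
  if (!all(c("mean_current", "variance") %in% names(pairs)))
    abort("`pairs` needs columns mean_current and variance.")
  pairs <- pairs[is.finite(pairs$mean_current) & is.finite(pairs$variance), ]
  if (nrow(pairs) < 3) abort("need at least 3 finite variance-mean pairs.")
  # equal-count bins; the quadratic basis is averaged inside each bin so
  # exact parabola input stays exact under binning (the model is linear
  # in parameters)
  binned <- if (nrow(pairs) > n_bins) {
    pairs |>
      dplyr::arrange(.data$mean_current) |>
      dplyr::mutate(bin = ceiling(dplyr::row_number() * n_bins /
                                    dplyr::n())) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(mean_sq = mean(.data$mean_current^2),
                       mean_current = mean(.data$mean_current),
                       variance = mean(.data$variance), .groups = "drop")
  } else {
    dplyr::mutate(dplyr::select(pairs, "mean_current", "variance"),
                  mean_sq = .data$mean_current^2)
  }
  if (nrow(binned) < 3) abort("need at least 3 bins with finite variance.")
  fit <- lm(variance ~ mean_current + mean_sq, data = binned)
  cf <- coef(fit)
  b <- cf[[3]]
  curv_tol <- 1e-10 * max(abs(binned$variance)) / max(binned$mean_sq)
  if (!is.finite(b) || b >= -curv_tol)
    abort("non-parabolic variance: no downward curvature, cannot estimate channel count.")
  var_b <- cf[[1]]
  if (var_b < -1e-6 * max(abs(binned$variance)))
    message("note: fitted baseline variance is negative (", signif(var_b, 3), " pA^2).")
  sst <- sum((binned$variance - mean(binned$variance))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(i = cf[[2]], n_channels = -1 / b, var_baseline = var_b,
         binned = binned,
         r_squared = r2,
         n_pairs = nrow(pairs), n_bins = nrow(binned)),
    class = "nsfa_result"
  )
}

#' Run peak-scaled fluctuation analysis on one cell
#'
#' Convenience wrapper: peak-aligned averaging of clean-decay events,
#' variance extraction over the decay window, and the parabola fit.
#'
#' @param events Flagged event tibble.
#' @param trace Source trace.
#' @param n_bins,window_frac,min_events See [parabola_fit()] and
#'   [peak_scaled_variance()].
#' @param pre_ms,post_ms Alignment window, ms.
#' @return An `nsfa_result`.
#' @export
nsfa <- function(events, trace, n_bins = 50, window_frac = 0.1,
                 min_events = 25, pre_ms = 5, post_ms = 60) {
  aligned <- average_waveform(events, trace, align = "peak",
                              pre_ms = pre_ms, post_ms = post_ms,
                              use = "clean_decay")
  pairs <- peak_scaled_variance(aligned, window_frac = window_frac,
                                min_events = min_events)
  res <- parabola_fit(pairs, n_bins = n_bins)
  res$n_events <- nrow(aligned$matrix)
  res
}
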