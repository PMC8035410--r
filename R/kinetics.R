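#' Fit a multi-exponential decay
#'
#' Fits `current(t) = offset + sum_k a_k exp(-t/tau_k)` to a decay segment
#' by variable projection: for trial decay constants the amplitudes (and
#' offset) are solved by linear least squares, and the decay constants are
#' optimized on a log scale by Nelder-Mead from several log-spaced
#' multi-starts.  The number of components is the smallest one for which
#' adding a further component fails to reduce the sum of squared errors by
#' at least `sse_tol` (relative); this mirrors the practice of accepting
#' an extra component only when it buys a real SSE reduction.
#'
#' @param decay A trace tibble starting at the peak and trending toward
#'   baseline.
#' @param max_components Maximum number of exponential components (1-3).
#' @param offset Include a constant offset (steady-state plateau)?  Use
#'   `TRUE` for patch currents with a desensitization plateau, `FALSE` for
#'   synaptic decays that return to baseline.
#' @param sse_tol Relative SSE reduction required to accept one more
#'   component; default 0.02.
#' @param restarts Multi-start count per component number; default 5.
#' @return An object of class `exp_fit`: components tibble (`a`, `tau_ms`,
#'   ascending in tau), `offset`, `sse`, `n_components`.
#' @examples
#' t <- seq(0, 0.2, by = 1e-4)
#' d <- tibble::tibble(time = t, current = -80 * exp(-t / 0.01))
#' fit_exponentials(d)
#' @export
fit_exponentials <- function(decay, max_components = 3, offset = FALSE,
                             sse_tol = 0.02, restarts = 5) {
  check_trace(decay)
  t <- decay$time - decay$time[1]
  y <- decay$current
  if (diff(range(y)) <= 1e-8 * max(abs(y), 1))
    abort("insufficient decay: segment is flat, no time constant can be calculated.")
  span <- max(t)
  fits <- list()
  for (m in seq_len(max_components)) {
    fits[[m]] <- fit_exp_m(t, y, m, offset, restarts, span)
    if (m > 1) {
      prev <- fits[[m - 1]]$sse
      gain <- if (prev > 0) (prev - fits[[m]]$sse) / prev else 0
      if (gain < sse_tol) { fits[[m]] <- NULL; break }
    }
    if (fits[[m]]$sse < 1e-16 * sum(y^2)) break
  }
  best <- fits[[length(fits)]]
  ord <- order(best$tau)
  structure(
    list(components = tibble::tibble(a = best$a[ord],
                                     tau_ms = best$tau[ord] * 1000),
         offset = best$offset, sse = best$sse,
         n_components = length(best$tau)),
    class = "exp_fit"
  )
}

# variable projection for fixed component count: linear LS amplitudes given
# taus, Nelder-Mead on log(tau) with log-spaced multi-starts
fit_exp_m <- function(t, y, m, offset, restarts, span) {
  design <- function(tau) {
    X <- vapply(tau, function(tk) exp(-t / tk), numeric(length(t)))
    if (offset) cbind(X, 1) else X
  }
  sse_of <- function(ltau) {
    tau <- exp(ltau)
    if (any(!is.finite(tau)) || any(tau > 100 * span) || any(tau < 1e-7))
      return(sum(y^2) * 10)
    X <- design(tau)
    fit <- tryCatch(stats::.lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) return(sum(y^2) * 10)
    sum(fit$residuals^2)
  }
  lo <- log(span / 500); hi <- log(span * 2)
  starts <- lapply(seq_len(restarts), function(r) {
    base <- seq(lo, hi, length.out = m + 2)[2:(m + 1)]
    base + (r - 1) * (hi - lo) / (4 * restarts) * rep_len(c(1, -1), m)
  })
  best <- NULL
  for (s in starts) {
    res <- if (m == 1) {
      o <- optimize(function(l) sse_of(l), c(lo - 2, hi + 1), tol = 1e-12)
      list(par = o$minimum, value = o$objective)
    } else {
      o <- stats::optim(s, sse_of, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
      list(par = o$par, value = o$value)
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  tau <- exp(best$par)
  X <- design(tau)
  cf <- stats::.lm.fit(X, y)$coefficients
  list(a = cf[seq_len(m)], tau = tau,
       offset = if (offset) cf[m + 1] else 0, sse = best$value)
}

#' Amplitude-weighted decay time constant
#'
#' `T_w = sum(a_k * tau_k) / sum(a_k)`: the weighted mean of the component
#' time constants, the standard scalar summary of a multi-exponential
#' decay.  Invariant to uniform rescaling of the amplitudes.
#'
#' @param fit An `exp_fit`, or a numeric vector of amplitudes.
#' @param tau_ms Time constants (ms) when `fit` is an amplitude vector.
#' @return Weighted time constant in ms.
#' @examples
#' weighted_tau(c(3, 1), c(10, 50))  # 20 ms
#' @export
weighted_tau <- function(fit, tau_ms = NULL) {
  if (inherits(fit, "exp_fit")) {
    a <- fit$components$a; tau_ms <- fit$components$tau_ms
  } else a <- fit
  if (length(a) != length(tau_ms) || !length(a))
    abort("amplitudes and time constants must match and be non-empty.")
  if (abs(sum(a)) < 1e-300) abort("amplitudes sum to zero; T_w is undefined.")
  sum(a * tau_ms) / sum(a)
}

#' Extent of desensitization
#'
#' The percentage reduction of the current from its peak to the steady
#' state, `(1 - steady/peak) * 100`.  Uses the ratio only, so it is
#' invariant to the sign convention of the current.
#'
#' @param peak Peak current, pA (non-zero).
#' @param steady Steady-state current, pA, same sign as `peak`.
#' @return Extent of desensitization, percent.
#' @examples
#' desens_extent(-100, -44.4)  # 55.6
#' @export
desens_extent <- function(peak, steady) {
  if (any(peak == 0)) abort("`peak` must be non-zero.")
  if (any(sign(peak) * sign(steady) < 0))
    abort("`peak` and `steady` must have the same sign.")
  (1 - steady / peak) * 100
}

#' Average aligned event waveforms
#'
#' Cuts a fixed window around each eligible event, aligns the snippets on
#' their peaks (or onsets), and returns the mean waveform together with
#' the aligned event matrix that fluctuation analysis consumes.
#'
#' @param events Flagged event tibble; only rows passing `use` are used.
#' @param trace Source trace.
#' @param align `"peak"` or `"onset"`.
#' @param pre_ms,post_ms Window before/after the alignment point, ms.
#' @param use Flag column gating eligibility (`"clean_decay"`,
#'   `"clean_rise"`, or `"all"`).
#' @return A list: `mean` (trace tibble, time 0 at the alignment point),
#'   `matrix` (events x samples), `events` (the rows used).
#' @export
average_waveform <- function(events, trace, align = c("peak", "onset"),
                             pre_ms = 5, post_ms = 60, use = "clean_decay") {
  align <- match.arg(align)
  check_trace(trace)
  rate <- trace_rate(trace)
  keep <- if (use == "all") rep(TRUE, nrow(events)) else isTRUE_vec(events[[use]])
  ev <- events[keep, , drop = FALSE]
  npre <- round(pre_ms / 1000 * rate); npost <- round(post_ms / 1000 * rate)
  centers <- round(((if (align == "peak") ev$t_peak else ev$onset) -
                      trace$time[1]) * rate) + 1L
  ok <- centers - npre >= 1 & centers + npost <= nrow(trace)
  ev <- ev[ok, , drop = FALSE]; centers <- centers[ok]
  if (nrow(ev) < 2) abort("fewer than 2 eligible events to average.")
  M <- t(vapply(centers, function(c0)
    trace$current[(c0 - npre):(c0 + npost)], numeric(npre + npost + 1)))
  list(
    mean = tibble::tibble(time = (seq_len(ncol(M)) - 1 - npre) / rate,
                          current = colMeans(M)),
    matrix = M, events = ev, peak_index = npre + 1L
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Paired-pulse re-sensitization curve
#'
#' From paired-pulse traces at several inter-pulse intervals, measures the
#' first-pulse peak from the pre-first-pulse baseline and the second-pulse
#' peak from the local current level just before the second pulse, and
#' returns their ratio per interval.  Optionally fits the recovery curve
#' `ratio = 1 - d * exp(-interval/tau_rec)`.
#'
#' @param pp Tibble from [simulate_paired_pulse()] (columns `interval`,
#'   `time`, `current`), or equivalent with attribute `"protocols"`.
#' @param fit Fit the single-exponential recovery?
#' @return An object of class `recovery_curve`: tibble (`interval`,
#'   `peak1`, `peak2`, `ratio`) plus, if fitted, `d` and `tau_rec_s`.
#' @export
pp_recovery <- function(pp, fit = TRUE) {
  protos <- attr(pp, "protocols")
  if (is.null(protos)) abort("`pp` must carry per-interval protocol metadata.")
  ivs <- unique(pp$interval)
  rows <- purrr::map2_dfr(ivs, protos, function(iv, proto) {
    d <- dplyr::filter(pp, .data$interval == iv)
    on <- proto$pulses$onset
    base1 <- mean(d$current[d$time < on[1]])
    win1 <- d$time >= on[1] & d$time < on[2] - 0.002
    peak1 <- min(d$current[win1]) - base1
    pre2 <- d$time >= on[2] - 0.002 & d$time < on[2]
    base2 <- mean(d$current[pre2])
    win2 <- d$time >= on[2]
    peak2 <- min(d$current[win2]) - base2
    tibble::tibble(interval = iv, peak1 = peak1, peak2 = peak2,
                   ratio = peak2 / peak1)
  })
  rows <- dplyr::arrange(rows, .data$interval)
  out <- structure(list(curve = rows, d = NA_real_, tau_rec_s = NA_real_),
                   class = "recovery_curve")
  if (fit && nrow(rows) >= 3 && any(rows$ratio < 0.98)) {
    fr <- fit_recovery(rows$interval, rows$ratio)
    out$d <- fr$d; out$tau_rec_s <- fr$tau_rec_s
  }
  out
}

#' Fit a single-exponential recovery curve
#'
#' Least-squares fit of `ratio = 1 - d * exp(-interval/tau)`.
#'
#' @param interval Intervals, s.
#' @param ratio Paired-pulse ratios.
#' @return A list with `d`, `tau_rec_s`, `rmse`.
#' @export
fit_recovery <- function(interval, ratio) {
  d0 <- max(1 - min(ratio), 0.05)
  tau0 <- max(median(interval), 1e-3)
  fit <- minpack.lm::nlsLM(
    ratio ~ 1 - d * exp(-interval / tau),
    start = list(d = d0, tau = tau0),
    lower = c(0, 1e-4), upper = c(1.5, 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  list(d = unname(cf["d"]), tau_rec_s = unname(cf["tau"]),
       rmse = sqrt(mean(stats::residuals(fit)^2)))
}
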