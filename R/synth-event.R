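#' Define a binomial channel ensemble
#'
#' The generative model behind simulated synaptic events: `n_channels`
#' identical receptors, each passing unitary current `i` (pA, negative for
#' inward chloride flux) when open.  The open-probability time course is a
#' difference of exponentials, `p(t) = p_peak * (sum_k a_k exp(-t/tau_k) -
#' exp(-t/tau_rise)) / max`, i.e. a rising phase with time constant
#' `tau_rise_ms` and a (possibly multi-component) decay, normalised so the
#' peak open probability equals `p_peak`.
#'
#' At every sample the number of open channels is drawn independently as
#' Binomial(N, p(t)), so the across-event variance at mean current I obeys
#' the parabola `sigma^2 = i*I - I^2/N` exactly — the ground truth against
#' which peak-scaled fluctuation analysis is validated.
#'
#' @param n_channels Integer >= 1, number of channels (N).
#' @param i Unitary current in pA (negative for inward).
#' @param tau_rise_ms Rise time constant, ms.
#' @param decay Data frame with columns `a` (weights summing to 1) and
#'   `tau_ms` (decay time constants, ms).
#' @param p_peak Peak open probability in (0, 1].
#' @return An object of class `channel_ensemble`.
#' @examples
#' ens <- channel_ensemble(26, -3.33)
#' @export
channel_ensemble <- function(n_channels, i, tau_rise_ms = 0.8,
                             decay = data.frame(a = 1, tau_ms = 15),
                             p_peak = 0.8) {
  if (n_channels < 1 || n_channels != round(n_channels))
    abort("`n_channels` must be a positive integer.")
  if (abs(sum(decay$a) - 1) > 1e-8) abort("decay weights `a` must sum to 1.")
  if (any(decay$tau_ms <= 0) || tau_rise_ms <= 0)
    abort("time constants must be positive.")
  if (p_peak <= 0 || p_peak > 1) abort("`p_peak` must lie in (0, 1].")
  structure(
    list(n_channels = as.integer(n_channels), i = i,
         tau_rise_ms = tau_rise_ms, decay = decay, p_peak = p_peak),
    class = "channel_ensemble"
  )
}

# open-probability waveform at times t (s, from event onset)
p_wave <- function(ensemble, t) {
  tr <- ensemble$tau_rise_ms / 1000
  td <- ensemble$decay$tau_ms / 1000
  a <- ensemble$decay$a
  raw <- function(tt) {
    out <- -exp(-tt / tr)
    for (k in seq_along(a)) out <- out + a[k] * exp(-tt / td[k])
    out
  }
  # peak of the difference-of-exponentials, found on the rise/decay scale
  pk <- optimize(raw, c(0, 6 * max(td)), maximum = TRUE)
  p <- numeric(length(t))
  pos <- t >= 0
  p[pos] <- ensemble$p_peak * raw(t[pos]) / pk$objective
  pmin(pmax(p, 0), 1)
}

p_wave_peak_time <- function(ensemble) {
  td <- max(ensemble$decay$tau_ms) / 1000
  optimize(function(tt) p_wave(ensemble, tt), c(0, 6 * td), maximum = TRUE)$maximum
}

#' Simulate one synaptic event from a channel ensemble
#'
#' Draws the open-channel count independently at every sample,
#' `Binomial(N, p(t))`, and returns the current trace `i * count` plus
#' optional white Gaussian baseline noise.
#'
#' @param ensemble A [channel_ensemble()].
#' @param rate Sampling rate, Hz.
#' @param duration Trace length, s.
#' @param noise_sd Baseline noise SD, pA.
#' @param t_onset Event onset time within the trace, s.
#' @param seed Optional integer seed for reproducibility.
#' @return A trace tibble with attribute `"open_counts"` (the latent open
#'   channel counts).
#' @export
simulate_event <- function(ensemble, rate = 10000, duration = 0.15,
                           noise_sd = 0, t_onset = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  p <- p_wave(ensemble, t - t_onset)
  counts <- rbinom(length(p), ensemble$n_channels, p)
  cur <- ensemble$i * counts
  if (noise_sd > 0) cur <- cur + rnorm(length(cur), sd = noise_sd)
  out <- tibble::tibble(time = t, current = cur)
  attr(out, "open_counts") <- counts
  out
}

#' Simulate a set of isolated, peak-aligned events
#'
#' Draws `n_events` independent events from one ensemble, locates each
#' realization's peak on a lightly smoothed copy, and returns them as a
#' peak-aligned event matrix in the same form as [average_waveform()] —
#' the direct input to [peak_scaled_variance()].  This bypasses detection
#' and is the standard route for validating fluctuation analysis against
#' the generative ground truth.
#'
#' @inheritParams simulate_event
#' @param n_events Number of events.
#' @param pre_ms,post_ms Window around the located peak, ms.
#' @param seed Integer seed.
#' @return A list with `mean`, `matrix`, `peak_index` (see
#'   [average_waveform()]).
#' @export
simulate_aligned_events <- function(ensemble, n_events = 300, rate = 10000,
                                    noise_sd = 2, pre_ms = 5, post_ms = 60,
                                    seed = 1) {
  set.seed(seed)
  npre <- round(pre_ms / 1000 * rate); npost <- round(post_ms / 1000 * rate)
  tpk <- p_wave_peak_time(ensemble)
  dur <- tpk + (pre_ms + post_ms + 10) / 1000
  onset <- (pre_ms + 5) / 1000
  sm <- max(3L, round(rate / 2000))
  kern <- rep(1 / sm, sm)
  M <- t(vapply(seq_len(n_events), function(k) {
    ev <- simulate_event(ensemble, rate = rate, duration = dur,
                         noise_sd = noise_sd, t_onset = onset)
    y <- ev$current
    ysm <- as.numeric(stats::filter(y, kern, sides = 2))
    search <- round((onset) * rate):round((onset + 2.5 * tpk) * rate)
    pk <- search[which.min(ysm[search])]
    y[(pk - npre):(pk + npost)]
  }, numeric(npre + npost + 1)))
  list(mean = tibble::tibble(time = (seq_len(ncol(M)) - 1 - npre) / rate,
                             current = colMeans(M)),
       matrix = M, peak_index = npre + 1L)
}

#' Configure a simulated sIPSC train
#'
#' Event times follow independent homogeneous Poisson processes, one per
#' event class; classes may differ in rate, kinetics and amplitude scale so
#' that cluster-structured trains can be generated.  Defaults emulate a
#' control recording: ensemble of 26 channels at -3.33 pA unitary current
#' (mean peak near -55 pA for p_peak 0.8 after binomial thinning), event
#' rate ~1 Hz and 2 pA baseline noise.
#'
#' @param duration Sweep length, s.
#' @param classes A tibble with one row per event class: columns `rate`
#'   (Hz) and `ensemble` (list-column of [channel_ensemble()] objects);
#'   optional `label`.
#' @param noise_sd Baseline Gaussian noise SD, pA.
#' @param rate Sampling rate, Hz.
#' @return An object of class `train_config`.
#' @export
train_config <- function(duration = 100,
                         classes = tibble::tibble(
                           label = "ctrl", rate = 1,
                           ensemble = list(channel_ensemble(26, -3.33))),
                         noise_sd = 2, rate = 10000) {
  if (any(classes$rate <= 0)) abort("class event rates must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!"label" %in% names(classes))
    classes$label <- paste0("class", seq_len(nrow(classes)))
  structure(list(duration = duration, classes = classes,
                 noise_sd = noise_sd, rate = rate),
            class = "train_config")
}

#' Simulate an sIPSC train with ground truth
#'
#' Lays Poisson event times per class, draws each event from its binomial
#' channel ensemble, sums them onto a common trace, adds baseline noise,
#' and returns both the trace and a ground-truth event table (onset, class,
#' the event's own noiseless peak amplitude and peak time).
#'
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return A list with `trace` (tibble) and `truth` (tibble: `onset`,
#'   `t_peak`, `amplitude`, `class`), ordered by onset.
#' @export
simulate_train <- function(config, seed = 1) {
  set.seed(seed)
  rate <- config$rate
  n <- round(config$duration * rate)
  t <- (seq_len(n) - 1) / rate
  cur <- numeric(n)
  rows <- list()
  for (ci in seq_len(nrow(config$classes))) {
    cls <- config$classes[ci, ]
    ens <- cls$ensemble[[1]]
    n_ev <- rpois(1, cls$rate * config$duration)
    if (n_ev == 0) next
    onsets <- sort(runif(n_ev, 0, config$duration))
    span <- min(n, round((p_wave_peak_time(ens) +
                            6 * max(ens$decay$tau_ms) / 1000) * rate))
    tt <- (seq_len(span) - 1) / rate
    p <- p_wave(ens, tt)
    for (ev in seq_len(n_ev)) {
      i0 <- round(onsets[ev] * rate) + 1
      idx <- i0:min(n, i0 + span - 1)
      counts <- rbinom(length(idx), ens$n_channels, p[seq_along(idx)])
      wave <- ens$i * counts
      cur[idx] <- cur[idx] + wave
      pk <- which.max(abs(wave))
      rows[[length(rows) + 1]] <- tibble::tibble(
        onset = t[i0], t_peak = t[idx[pk]], amplitude = wave[pk],
        class = cls$label)
    }
  }
  if (config$noise_sd > 0) cur <- cur + rnorm(n, sd = config$noise_sd)
  truth <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows), .data$onset)
           else tibble::tibble(onset = numeric(), t_peak = numeric(),
                               amplitude = numeric(), class = character())
  if (!nrow(truth))
    warn("simulated duration produced no events; ground-truth table is empty.")
  list(trace = tibble::tibble(time = t, current = cur), truth = truth)
}
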