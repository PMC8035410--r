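# shared fixtures, all generated in code

# an idealised noiseless event A * (1 - exp(-t/tr)) * exp(-t/td) laid on a
# flat baseline; closed-form enough for oracle root-finding on rise times
ideal_event_trace <- function(amp = -100, tr_ms = 0.5, td_ms = 20,
                              rate = 50000, duration = 0.25,
                              onset = 0.05) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  te <- pmax(t - onset, 0)
  cur <- amp * (1 - exp(-te * 1000 / tr_ms)) * exp(-te * 1000 / td_ms)
  cur[t < onset] <- 0
  tibble::tibble(time = t, current = cur)
}

# 3-component 2-D skew-t mixture with separated locations, distinct
# skews, nu = 6: the clustering fixture
skewt_fixture <- function(n = 600, seed = 1) {
  set.seed(seed)
  ns <- drop(stats::rmultinom(1, n, c(0.5, 0.3, 0.2)))
  X <- rbind(
    rmst(ns[1], c(0, 0), diag(2), c(2, 0.5), 6),
    rmst(ns[2], c(6, 5), matrix(c(1, .3, .3, 1), 2), c(-1.5, 1), 6),
    rmst(ns[3], c(-4, 6), diag(c(0.5, 1.5)), c(0.5, -2), 6)
  )
  list(X = X, labels = rep(1:3, ns))
}

# greedy 1-1 matching of detected to true peaks within a tolerance (s)
match_events <- function(detected, truth, tol = 0.005) {
  used <- rep(FALSE, nrow(detected))
  hits <- 0L
  for (tp in truth$t_peak) {
    d <- abs(detected$t_peak - tp)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = hits / nrow(truth), precision = hits / nrow(detected))
}

# literal signal-to-noise-10 train: stereotyped waveform (gating noise
# negligible at 4000 channels), Gaussian baseline noise at peak/10
snr10_train <- function(duration = 100, seed = 1, rate = 10000) {
  ens <- channel_ensemble(4000, -55 / (4000 * 0.8), p_peak = 0.8)
  cfg <- train_config(
    duration = duration, noise_sd = 5.5, rate = rate,
    classes = tibble::tibble(label = "a", rate = 1, ensemble = list(ens))
  )
  simulate_train(cfg, seed = seed)
}
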