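test_that("rise times of an ideal event match root-finding on the closed form", {
  amp <- -100; tr_ms <- 0.5; td_ms <- 20; rate <- 50000
  tr <- ideal_event_trace(amp, tr_ms, td_ms, rate = rate)
  det <- detect_events(tr, event_template(rise_ms = 0.5, decay_ms = 20))
  expect_equal(nrow(det), 1)
  ev <- extract_features(flag_selection(det, tr), tr)

  # oracle: root-find the fractional crossings of the closed-form wave
  f <- function(tt) (1 - exp(-tt / tr_ms)) * exp(-tt / td_ms)
  tpk <- uniroot(function(tt) f(tt + 1e-7) - f(tt - 1e-7),
                 c(0.5, 20), tol = 1e-10)$root
  fpk <- f(tpk)
  crossing <- function(frac)
    uniroot(function(tt) f(tt) - frac * fpk, c(1e-6, tpk), tol = 1e-12)$root
  r2080 <- crossing(0.8) - crossing(0.2)
  r1090 <- crossing(0.9) - crossing(0.1)
  r3070 <- crossing(0.7) - crossing(0.3)

  dt_ms <- 1000 / rate
  expect_equal(ev$rise_20_80, r2080, tolerance = dt_ms / r2080)
  expect_equal(ev$rise_10_90, r1090, tolerance = dt_ms / r1090)
  expect_equal(ev$rise_30_70, r3070, tolerance = dt_ms / r3070)
})

test_that("rise-time ordering invariant holds table-wide on noisy trains", {
  sim <- snr10_train(duration = 60, seed = 9)
  tr <- subtract_baseline(sim$trace, c(0, 0.05))
  ev <- extract_features(flag_selection(detect_events(tr, event_template()), tr), tr)
  ok <- complete.cases(ev[, c("rise_10_90", "rise_20_80", "rise_30_70")])
  expect_gt(sum(ok), 20)
  expect_true(all(ev$rise_30_70[ok] <= ev$rise_20_80[ok] + 1e-12))
  expect_true(all(ev$rise_20_80[ok] <= ev$rise_10_90[ok] + 1e-12))
})

test_that("burst window equals the brute-force triplet oracle", {
  # spec'd arithmetic case: peaks at 0, 0.5, 1.0, 5.0 s
  bw <- synaptoscope:::burst_windows(c(0, 0.5, 1, 5))
  expect_equal(bw$window[2], 1.0)

  # oracle equivalence on a large random table
  set.seed(13)
  tp <- sort(cumsum(rexp(1000, 2)))
  bw2 <- synaptoscope:::burst_windows(tp)
  brute <- vapply(seq_along(tp), function(k) {
    starts <- max(1, k - 2):min(k, length(tp) - 2)
    min(tp[starts + 2] - tp[starts])
  }, numeric(1))
  expect_equal(bw2$window, brute)
  # burst window always >= the tightest triplet's own span by definition
  expect_true(all(bw2$window >= 0))
  # CV of the chosen triplet's two intervals
  k <- 17
  starts <- (k - 2):k
  j <- starts[which.min(tp[starts + 2] - tp[starts])]
  ints <- diff(tp[j:(j + 2)])
  expect_equal(bw2$cv[k], sd(ints) / mean(ints))
})

test_that("IEI and instantaneous frequency are reciprocal; first event missing", {
  tr <- new_trace(rep(0, 30000), 10000)
  ev <- tibble::tibble(event = 1:3, onset = c(0.5, 1.0, 1.5) - 0.002,
                       t_peak = c(0.5, 1.0, 1.5),
                       amplitude = c(-50, -50, -50), criterion = c(9, 9, 9))
  out <- extract_features(ev, tr)
  expect_true(is.na(out$iei[1]))
  expect_equal(out$iei[2:3], c(0.5, 0.5))
  expect_equal(out$inst_freq[2:3], c(2, 2))
})

test_that("a notch on the rising phase clears the clean_rise flag", {
  rate <- 20000
  t <- seq(0, 0.4 - 1 / rate, by = 1 / rate)
  te <- pmax(t - 0.2, 0) * 1000
  base <- -100 * (1 - exp(-te / 1.5)) * exp(-te / 20)
  # inject a plateau/reversal in mid-rise
  notch <- base
  mid <- t >= 0.2006 & t <= 0.2012
  notch[mid] <- notch[t >= 0.2][1] * 0.3
  tr_clean <- tibble::tibble(time = t, current = base)
  tr_notch <- tibble::tibble(time = t, current = notch)
  tmpl <- event_template(rise_ms = 1, decay_ms = 20)
  fc <- flag_selection(detect_events(tr_clean, tmpl), tr_clean)
  fn <- flag_selection(detect_events(tr_notch, tmpl), tr_notch)
  expect_true(fc$clean_rise[1] && fc$clean_decay[1])
  expect_false(fn$clean_rise[1])
})

test_that("truncated edge events get missing features", {
  rate <- 10000
  t <- seq(0, 0.3 - 1 / rate, by = 1 / rate)
  te <- pmax(t - 0.295, 0) * 1000
  cur <- -80 * (1 - exp(-te / 0.8)) * exp(-te / 15)
  tr <- tibble::tibble(time = t, current = cur)
  ev <- tibble::tibble(event = 1L, onset = 0.295, t_peak = 0.2999,
                       amplitude = -80, criterion = 10)
  out <- extract_features(ev, tr)
  expect_true(is.na(out$rise_20_80) || out$t_peak < max(t))
})
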