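test_that("single channel at full open probability passes the unitary current", {
  ens <- channel_ensemble(1, -3, p_peak = 1,
                          decay = data.frame(a = 1, tau_ms = 1e9),
                          tau_rise_ms = 1e-3)
  tr <- simulate_event(ens, rate = 1000, duration = 0.5,
                       t_onset = 0.1, seed = 1)
  late <- tr$current[tr$time > 0.2]
  expect_true(all(late == -3))
})

test_that("binomial peak statistics match the closed form", {
  # N = 60, i = -3, p_peak = 0.9: mean of simulated peak-sample currents
  # is N*i*p = -162 within Monte Carlo error
  ens <- channel_ensemble(60, -3, p_peak = 0.9)
  tpk <- synaptoscope:::p_wave_peak_time(ens)
  set.seed(7)
  n_ev <- 2000
  peaks <- vapply(seq_len(n_ev), function(k) {
    tr <- simulate_event(ens, rate = 2000, duration = tpk + 0.002)
    tr$current[which.min(abs(tr$time - tpk))]
  }, numeric(1))
  se <- 3 * sqrt(60 * 0.9 * 0.1 / n_ev)
  expect_lt(abs(mean(peaks) - (-162)), 4 * se)

  # across-event variance at p = 0.5, N = 50, i = -2 -> 50 pA^2
  ens2 <- channel_ensemble(50, -2, p_peak = 0.5)
  tpk2 <- synaptoscope:::p_wave_peak_time(ens2)
  peaks2 <- vapply(seq_len(n_ev), function(k) {
    tr <- simulate_event(ens2, rate = 2000, duration = tpk2 + 0.002)
    tr$current[which.min(abs(tr$time - tpk2))]
  }, numeric(1))
  expect_lt(abs(var(peaks2) - 50), 6)   # var of var MC allowance
})

test_that("trains are seed-deterministic with Poisson class thinning", {
  cfg <- train_config(duration = 30, noise_sd = 1)
  a <- simulate_train(cfg, seed = 5)
  b <- simulate_train(cfg, seed = 5)
  expect_identical(a$trace$current, b$trace$current)
  expect_identical(a$truth, b$truth)

  # two classes at 0.5/1.5 Hz: class-2 fraction ~ 0.75
  cfg2 <- train_config(
    duration = 400, noise_sd = 0, rate = 2000,
    classes = tibble::tibble(
      label = c("slow", "fast"), rate = c(0.5, 1.5),
      ensemble = list(channel_ensemble(20, -3), channel_ensemble(20, -3))
    )
  )
  tra <- simulate_train(cfg2, seed = 11)
  frac <- mean(tra$truth$class == "fast")
  n <- nrow(tra$truth)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("noiseless ground-truth peaks equal i times the open count", {
  cfg <- train_config(duration = 20, noise_sd = 0)
  sim <- simulate_train(cfg, seed = 3)
  # every true amplitude is an integer multiple of i
  mult <- sim$truth$amplitude / -3.33
  expect_equal(mult, round(mult), tolerance = 1e-9)
})

test_that("occupancies are conserved and the C-O-D solution is exact", {
  sch <- kinetic_scheme(beta = 5000, alpha = 400, delta = 300, rho = 1)
  pp <- simulate_paired_pulse(sch, intervals = 0.5, mode = "deterministic")
  occ_sum <- pp$occ_C + pp$occ_O + pp$occ_D
  expect_equal(occ_sum, rep(1, nrow(pp)), tolerance = 1e-8)

  # no desensitization: paired-pulse ratio is 1 at every interval
  nd <- preset_scheme("non_desensitizing")
  rc <- pp_recovery(simulate_paired_pulse(nd, c(0.1, 0.5, 2)), fit = FALSE)
  expect_equal(rc$curve$ratio, rep(1, 3), tolerance = 1e-6)
})

test_that("stochastic mean converges to the deterministic occupancies", {
  sch <- preset_scheme("wild_type")
  det <- simulate_paired_pulse(sch, 0.5, mode = "deterministic")
  sto <- simulate_paired_pulse(sch, 0.5, mode = "stochastic",
                               n_trials = 400, n_channels = 100, seed = 2)
  # binomial MC standard error per occupancy, bounded over the trace
  se <- sqrt(pmax(det$occ_O * (1 - det$occ_O), 1e-4) / (400 * 100))
  dev <- abs(sto$occ_O - det$occ_O)
  expect_lt(mean(dev > 3 * se), 0.01)
  expect_lt(max(dev), 6 * max(se))
})

test_that("preset regimes order paired-pulse suppression correctly", {
  ivs <- c(0.5, 1, 2)
  ratio_at <- function(regime)
    pp_recovery(simulate_paired_pulse(preset_scheme(regime), ivs),
                fit = FALSE)$curve$ratio
  r_non <- ratio_at("non_desensitizing")
  r_wt <- ratio_at("wild_type")
  r_hyp <- ratio_at("hyper_desensitizing")
  expect_true(all(r_hyp < r_wt))
  expect_true(all(r_wt < r_non + 1e-9))
})
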