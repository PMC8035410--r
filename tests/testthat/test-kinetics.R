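test_that("noiseless single exponential is recovered exactly", {
  t <- seq(0, 0.2, by = 2e-5)
  fit <- fit_exponentials(tibble::tibble(time = t, current = 80 * exp(-t / 0.01)))
  expect_equal(fit$n_components, 1)
  expect_equal(fit$components$tau_ms, 10, tolerance = 1e-3)
})

test_that("noiseless bi-exponential components are recovered within 1%", {
  t <- seq(0, 0.3, by = 5e-5)
  y <- 50 * exp(-t / 0.005) + 50 * exp(-t / 0.05)
  fit <- fit_exponentials(tibble::tibble(time = t, current = y))
  expect_equal(fit$n_components, 2)
  expect_equal(fit$components$tau_ms, c(5, 50), tolerance = 0.01)
  expect_equal(fit$components$a, c(50, 50), tolerance = 0.01)
})

test_that("flat segments raise the insufficient-decay error", {
  t <- seq(0, 0.1, by = 1e-4)
  expect_error(
    fit_exponentials(tibble::tibble(time = t, current = rep(-40, length(t)))),
    "insufficient decay")
})

test_that("weighted tau matches hand arithmetic and its invariants", {
  expect_equal(weighted_tau(1, 12), 12)
  expect_equal(weighted_tau(c(1, 1), c(10, 20)), 15)
  expect_equal(weighted_tau(c(3, 1), c(10, 50)), 20)   # (30+50)/4
  # homogeneity: rescaling amplitudes leaves T_w unchanged
  set.seed(2)
  for (k in 1:10) {
    a <- runif(3); tau <- sort(runif(3, 1, 100))
    expect_equal(weighted_tau(a, tau), weighted_tau(7.3 * a, tau))
    tw <- weighted_tau(a, tau)
    expect_gte(tw, min(tau)); expect_lte(tw, max(tau))
  }
  expect_error(weighted_tau(c(1, -1), c(5, 10)), "sum to zero")
})

test_that("desensitization extent follows the peak/steady-state ratio", {
  expect_equal(desens_extent(-100, -44.4), 55.6)
  expect_equal(desens_extent(-80, -80), 0)
  expect_equal(desens_extent(-80, 0), 100)
  # sign-convention invariance
  expect_equal(desens_extent(100, 44.4), desens_extent(-100, -44.4))
  expect_error(desens_extent(0, -10), "non-zero")
  expect_error(desens_extent(-50, 10), "same sign")
})

test_that("averaged waveforms behave under duplication and scaling", {
  rate <- 10000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  te1 <- pmax(t - 0.5, 0) * 1000; te2 <- pmax(t - 1.4, 0) * 1000
  shape <- function(te) (1 - exp(-te / 0.8)) * exp(-te / 15)
  cur <- -50 * shape(te1) - 100 * shape(te2)
  tr <- tibble::tibble(time = t, current = cur)
  pk <- function(on) t[which.min(abs(cur - min(cur[t >= on & t < on + 0.05])))]
  ev <- tibble::tibble(event = 1:2, onset = c(0.5, 1.4),
                       t_peak = c(t[t >= 0.5][which.min(cur[t >= 0.5 & t < 0.55])],
                                  t[t >= 1.4][which.min(cur[t >= 1.4 & t < 1.45])]),
                       amplitude = c(-50, -100), criterion = c(9, 9),
                       clean_rise = TRUE, clean_decay = TRUE)
  aw <- average_waveform(ev, tr, align = "peak", post_ms = 40)
  expect_equal(nrow(aw$matrix), 2)
  # amplitudes are -50/-100 times the peak of the normalised shape
  shape_pk <- max(shape(seq(0, 20, by = 0.01)))
  expect_equal(min(aw$mean$current), -75 * shape_pk, tolerance = 0.01)
  expect_error(average_waveform(ev[1, ], tr), "fewer than 2")
})

test_that("paired-pulse ratios and recovery fits track the generative scheme", {
  # closed-form spec case: d = 0.6, tau_rec = 2 s, interval 2 s -> 0.779
  ivs <- c(0.25, 0.5, 1, 2, 4, 8)
  ratio <- 1 - 0.6 * exp(-ivs / 2)
  fr <- fit_recovery(ivs, ratio)
  expect_equal(fr$d, 0.6, tolerance = 1e-6)
  expect_equal(fr$tau_rec_s, 2, tolerance = 1e-6)
  expect_equal(1 - 0.6 * exp(-1), 0.779, tolerance = 1e-3)

  # deterministic C-O-D recovery is single-exponential in rho once the
  # open state has emptied: fitted tau matches 1/rho to ~1%
  sch <- preset_scheme("wild_type")
  rc <- pp_recovery(simulate_paired_pulse(sch, ivs))
  expect_equal(rc$tau_rec_s, 1 / sch$rho, tolerance = 0.02)
  fitted <- 1 - rc$d * exp(-ivs / rc$tau_rec_s)
  expect_lt(sqrt(mean((fitted - rc$curve$ratio)^2)), 1e-3)
})

test_that("stochastic recovery parameters match deterministic ground truth within 15%", {
  sch <- preset_scheme("wild_type")
  ivs <- c(0.1, 0.25, 0.5, 1, 2, 4)
  rd <- pp_recovery(simulate_paired_pulse(sch, ivs, mode = "deterministic"))
  rs <- pp_recovery(simulate_paired_pulse(sch, ivs, mode = "stochastic",
                                          n_trials = 200, seed = 8))
  expect_lt(abs(rs$d - rd$d) / rd$d, 0.15)
  expect_lt(abs(rs$tau_rec_s - rd$tau_rec_s) / rd$tau_rec_s, 0.15)
  rmse <- sqrt(mean((rs$curve$ratio -
                       (1 - rd$d * exp(-ivs / rd$tau_rec_s)))^2))
  expect_lt(rmse, 0.05)
})
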