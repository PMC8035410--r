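test_that("trace constructor validates and builds a uniform time base", {
  tr <- new_trace(c(-1, -2, -3), rate = 1000, t0 = 0.5)
  expect_equal(tr$time, c(0.5, 0.501, 0.502))
  expect_equal(trace_rate(tr), 1000)
  expect_error(new_trace(c(1, NA), 1000), "finite")
  expect_error(new_trace(1, 1000), "at least 2")
  expect_error(new_trace(1:10, -5), "positive")
})

test_that("bessel filter has unit DC gain and normalised impulse response", {
  tr <- new_trace(rep(-10, 2000), rate = 50000)
  out <- bessel_filter(tr, cutoff = 5000, poles = 4)
  expect_equal(out$current, tr$current, tolerance = 1e-9)
  imp <- new_trace(c(rep(0, 99), 1, rep(0, 9900)), rate = 50000)
  h <- bessel_filter(imp, cutoff = 5000, poles = 4)
  expect_equal(sum(h$current), 1, tolerance = 1e-9)
})

test_that("analogue prototype matches an independent Bessel magnitude response", {
  # reference magnitudes computed with an independent analogue Bessel
  # design (magnitude-normalised), frozen at w = 0.25,0.5,1,2,4,8 rad/s
  ref4 <- c(0.980168857882, 0.922028053233, 0.707106781187,
            0.213663457258, 0.018980956682, 0.001260821464)
  ref8 <- c(9.791242497733e-01, 9.186893288145e-01, 7.071067811866e-01,
            2.071161694755e-01, 2.566907529743e-03, 1.122976908816e-05)
  w <- c(0.25, 0.5, 1, 2, 4, 8)
  expect_equal(synaptoscope:::bessel_analog_gain(w, 4), ref4, tolerance = 1e-9)
  expect_equal(synaptoscope:::bessel_analog_gain(w, 8), ref8, tolerance = 1e-9)
})

test_that("digital 8-pole 2 kHz response matches the analogue prototype", {
  rate <- 50000
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  gain_at <- function(f) {
    tr <- tibble::tibble(time = t, current = sin(2 * pi * f * t))
    y <- bessel_filter(tr, 2000, poles = 8)$current
    # steady-state amplitude, skipping the filter transient
    max(abs(y[seq(rate / 2, rate)]))
  }
  g500 <- gain_at(500); g4k <- gain_at(4000)
  # the bilinear transform warps the frequency axis; the digital gain at f
  # equals the analogue prototype at tan(pi f/fs)/tan(pi fc/fs)
  warp <- function(f) tan(pi * f / rate) / tan(pi * 2000 / rate)
  ref <- synaptoscope:::bessel_analog_gain(warp(c(500, 4000)), 8)
  # sine-probe peak sampling quantises the measured amplitude by ~1%
  expect_equal(g500, ref[1], tolerance = 0.01)
  expect_equal(g4k, ref[2], tolerance = 0.01)
  # out-of-band power at twice the cutoff is suppressed ~20x
  expect_gt((g500 / g4k)^2, 15)
})

test_that("filtering is linear", {
  set.seed(1)
  x <- new_trace(rnorm(3000), 20000)
  y <- new_trace(rnorm(3000), 20000)
  fx <- bessel_filter(x, 2000, 8)$current
  fy <- bessel_filter(y, 2000, 8)$current
  mix <- x
  mix$current <- 2 * x$current - 3 * y$current
  fmix <- bessel_filter(mix, 2000, 8)$current
  expect_equal(fmix, 2 * fx - 3 * fy, tolerance = 1e-9)
})

test_that("cutoff at or above Nyquist is rejected", {
  tr <- new_trace(rnorm(100), 10000)
  expect_error(bessel_filter(tr, 5000, 4), "invalid filter")
  expect_error(bessel_filter(tr, 6000, 4), "invalid filter")
  expect_error(bessel_filter(tr, 2000, 6), "poles")
})

test_that("baseline subtraction zeroes the window mean and preserves shape", {
  tr <- new_trace(rep(-5, 1000), 10000)
  out <- subtract_baseline(tr, c(0, 0.05))
  expect_equal(out$current, rep(0, 1000))

  ev <- ideal_event_trace(rate = 10000)
  depth <- min(ev$current)
  ev$current <- ev$current - 5
  out2 <- subtract_baseline(ev, c(0, 0.04))
  expect_equal(mean(out2$current[out2$time <= 0.04]), 0, tolerance = 1e-12)
  expect_equal(min(out2$current), depth, tolerance = 1e-9)

  ramp <- new_trace(seq(0, 1, length.out = 1000), 1000)
  out3 <- subtract_baseline(ramp, c(0.2, 0.4))
  sel <- out3$time >= 0.2 & out3$time <= 0.4
  expect_equal(mean(out3$current[sel]), 0, tolerance = 1e-12)
  expect_gt(abs(mean(out3$current)), 1e-3)

  expect_error(subtract_baseline(tr, c(2, 3)), "no samples")
  expect_error(subtract_baseline(tr, c(0.05, 0.01)), "end > start")
})
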