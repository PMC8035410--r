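#' Three-state receptor gating scheme
#'
#' A minimal closed (C) - open (O) - desensitized (D) scheme for
#' macroscopic agonist-evoked currents: agonist drives C -> O at rate
#' `beta * u(t)` (with `u(t)` the agonist waveform), channels close
#' O -> C at `alpha`, desensitize O -> D at `delta`, and re-sensitize
#' D -> C at `rho`.  All rates in 1/s.  Occupancies always sum to 1.
#'
#' @param beta,alpha,delta,rho Transition rates (1/s), all >= 0.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(beta = 6000, alpha = 300, delta = 250, rho = 2) {
  rates <- c(beta = beta, alpha = alpha, delta = delta, rho = rho)
  if (any(!is.finite(rates)) || any(rates < 0))
    abort("all rates must be finite and >= 0.")
  structure(as.list(rates), class = "kinetic_scheme")
}

#' Preset gating regimes
#'
#' Qualitative regimes for paired-pulse behaviour: `"wild_type"` (moderate
#' desensitization, seconds-scale recovery), `"non_desensitizing"`
#' (delta = 0, paired-pulse ratio 1 at all intervals) and
#' `"hyper_desensitizing"` (deep desensitization with slow recovery, hence
#' the most sustained paired-pulse suppression).
#'
#' @param regime One of `"wild_type"`, `"non_desensitizing"`,
#'   `"hyper_desensitizing"`.
#' @return A [kinetic_scheme()].
#' @export
preset_scheme <- function(regime = c("wild_type", "non_desensitizing",
                                     "hyper_desensitizing")) {
  switch(match.arg(regime),
    wild_type           = kinetic_scheme(beta = 6000, alpha = 300, delta = 250, rho = 2),
    non_desensitizing   = kinetic_scheme(beta = 6000, alpha = 300, delta = 0,   rho = 2),
    hyper_desensitizing = kinetic_scheme(beta = 6000, alpha = 300, delta = 1200, rho = 0.4)
  )
}

#' Paired-pulse agonist protocol
#'
#' Two brief agonist pulses separated by a variable interval, the standard
#' probe of recovery from desensitization.
#'
#' @param interval Inter-pulse interval, onset to onset, s.
#' @param pulse_ms Pulse duration, ms.
#' @param t_first Onset of the first pulse, s.
#' @param agonist Agonist drive scale multiplying `beta` during pulses.
#' @param tail Recording time after the second pulse, s.
#' @return An object of class `protocol_spec` with a `pulses` tibble
#'   (`onset`, `duration`) and fields `agonist`, `t_end`.
#' @export
paired_pulse_protocol <- function(interval, pulse_ms = 1, t_first = 0.01,
                                  agonist = 1, tail = 0.08) {
  dur <- pulse_ms / 1000
  if (interval <= dur) abort("pulses must not overlap: interval > pulse duration.")
  structure(
    list(pulses = tibble::tibble(onset = c(t_first, t_first + interval),
                                 duration = dur),
         agonist = agonist,
         t_end = t_first + interval + dur + tail),
    class = "protocol_spec"
  )
}

# generator matrix (rows = from-state C, O, D) for agonist drive u in [0, inf)
scheme_generator <- function(scheme, u) {
  b <- scheme$beta * u
  matrix(c(-b,            b,                        0,
           scheme$alpha, -(scheme$alpha + scheme$delta), scheme$delta,
           scheme$rho,    0,                       -scheme$rho),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("C", "O", "D"), c("C", "O", "D")))
}

# occupancy propagation over one constant-agonist segment via the eigen
# decomposition of the generator (exact for piecewise-constant drive)
propagate_segment <- function(x0, Q, times) {
  e <- eigen(t(Q))
  Vi <- solve(e$vectors)
  co <- Vi %*% x0
  out <- vapply(times, function(tt)
    Re(e$vectors %*% (exp(e$values * tt) * co)), numeric(3))
  t(out)   # rows = times, cols = C, O, D
}

# split [0, t_end] into constant-drive segments from the pulse table
protocol_segments <- function(protocol) {
  brk <- sort(unique(c(0, protocol$pulses$onset,
                       protocol$pulses$onset + protocol$pulses$duration,
                       protocol$t_end)))
  brk <- brk[brk <= protocol$t_end + 1e-12]
  seg <- tibble::tibble(start = head(brk, -1), end = tail(brk, -1))
  seg$u <- vapply(seg$start, function(s)
    if (any(s >= protocol$pulses$onset - 1e-12 &
            s < protocol$pulses$onset + protocol$pulses$duration - 1e-12))
      protocol$agonist else 0, numeric(1))
  seg
}

#' Simulate a paired-pulse experiment
#'
#' Runs the C-O-D scheme through a paired-pulse protocol for each
#' inter-pulse interval.  In `"deterministic"` mode the occupancy
#' trajectories solve the linear kinetic equations exactly (matrix
#' exponential per constant-drive segment).  In `"stochastic"` mode
#' `n_trials` independent Gillespie realizations of `n_channels` channels
#' are run and the mean open-channel trajectory returned; the stochastic
#' mean converges to the deterministic solution as trials grow.
#'
#' @param scheme A [kinetic_scheme()].
#' @param intervals Inter-pulse intervals, s.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param n_trials Trials per interval (stochastic mode).
#' @param n_channels Channels per trial (stochastic mode).
#' @param i_unit Unitary current, pA (sets the current scale).
#' @param dt_out Output sample interval, s.
#' @param pulse_ms,agonist Passed to [paired_pulse_protocol()].
#' @param seed Integer seed (stochastic mode).
#' @return A tibble with columns `interval`, `time`, `current`, `occ_C`,
#'   `occ_O`, `occ_D`; attribute `"protocols"` holds the per-interval
#'   protocol objects.
#' @export
simulate_paired_pulse <- function(scheme, intervals,
                                  mode = c("deterministic", "stochastic"),
                                  n_trials = 200, n_channels = 100,
                                  i_unit = -1, dt_out = 2e-4,
                                  pulse_ms = 1, agonist = 1, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "stochastic") set.seed(seed)
  protos <- lapply(intervals, paired_pulse_protocol,
                   pulse_ms = pulse_ms, agonist = agonist)
  out <- purrr::map2_dfr(intervals, protos, function(iv, proto) {
    grid <- seq(0, proto$t_end, by = dt_out)
    occ <- if (mode == "deterministic") {
      pp_deterministic(scheme, proto, grid)
    } else {
      pp_stochastic(scheme, proto, grid, n_trials, n_channels)
    }
    tibble::tibble(interval = iv, time = grid,
                   current = i_unit * n_channels * occ[, "O"],
                   occ_C = occ[, "C"], occ_O = occ[, "O"], occ_D = occ[, "D"])
  })
  attr(out, "protocols") <- protos
  attr(out, "mode") <- mode
  out
}

pp_deterministic <- function(scheme, proto, grid) {
  seg <- protocol_segments(proto)
  x <- c(1, 0, 0)
  occ <- matrix(NA_real_, length(grid), 3,
                dimnames = list(NULL, c("C", "O", "D")))
  for (k in seq_len(nrow(seg))) {
    Q <- scheme_generator(scheme, seg$u[k])
    inseg <- which(grid >= seg$start[k] - 1e-12 & grid <= seg$end[k] + 1e-12)
    if (length(inseg))
      occ[inseg, ] <- propagate_segment(x, Q, grid[inseg] - seg$start[k])
    x <- drop(propagate_segment(x, Q, seg$end[k] - seg$start[k]))
  }
  stopifnot(max(abs(rowSums(occ) - 1)) < 1e-8)
  occ
}

# exact Gillespie on aggregate channel counts (channels are iid, so the
# count vector is itself Markov); one trajectory per trial
pp_stochastic <- function(scheme, proto, grid, n_trials, n_channels) {
  seg <- protocol_segments(proto)
  acc <- matrix(0, length(grid), 3)
  for (trial in seq_len(n_trials)) {
    n <- c(n_channels, 0L, 0L)   # C, O, D counts
    gi <- 1L
    for (k in seq_len(nrow(seg))) {
      t_now <- seg$start[k]; t_end <- seg$end[k]
      b <- scheme$beta * seg$u[k]
      repeat {
        r <- c(b * n[1], scheme$alpha * n[2], scheme$delta * n[2],
               scheme$rho * n[3])
        rt <- sum(r)
        t_next <- if (rt > 0) t_now + rexp(1, rt) else Inf
        while (gi <= length(grid) && grid[gi] <= min(t_next, t_end) + 1e-12) {
          acc[gi, ] <- acc[gi, ] + n
          gi <- gi + 1L
        }
        if (t_next > t_end) break
        t_now <- t_next
        j <- sample.int(4L, 1L, prob = r)
        if (j == 1L)      n <- n + c(-1L,  1L,  0L)
        else if (j == 2L) n <- n + c( 1L, -1L,  0L)
        else if (j == 3L) n <- n + c( 0L, -1L,  1L)
        else              n <- n + c( 1L,  0L, -1L)
      }
    }
  }
  occ <- acc / (n_trials * n_channels)
  colnames(occ) <- c("C", "O", "D")
  occ
}
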