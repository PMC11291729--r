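# Stochastic gating simulation: event-driven CTMC sample paths, ohmic
# current rendering with baseline noise and low-pass filtering, and a
# macroscopic (whole-cell) current generator.

# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Expand one root seed into k reproducible sub-seeds (one stream per channel).
expand_seed <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Gillespie sample path of a single channel: returns state-change times and
# states, starting from `state0` at t = 0, covering [0, duration].
sample_path <- function(q, state0, duration) {
  n_max <- 64L
  times <- numeric(n_max); states <- integer(n_max)
  t <- 0; s <- state0; k <- 0L
  repeat {
    k <- k + 1L
    if (k > n_max) {
      n_max <- n_max * 2L
      length(times) <- n_max; length(states) <- n_max
    }
    times[k] <- t; states[k] <- s
    exit <- -q[s, s]
    if (exit <= 0) break                      # no escape: dwell to the end
    t <- t + stats::rexp(1, exit)
    if (t >= duration) break
    p <- q[s, ]; p[s] <- 0
    s <- sample.int(length(p), 1, prob = p)
  }
  list(start_s = times[seq_len(k)], state = states[seq_len(k)])
}

#' Simulate channel gating as a continuous-time Markov chain
#'
#' Draws an exact, event-driven sample path (Gillespie algorithm; no time
#' discretization) for each of the model's N channels at a fixed command
#' voltage, and sums the per-channel conductance levels into an aggregate
#' idealized trace. Each channel starts from the stationary distribution of
#' the generator at that voltage, so finite windows of the path are
#' stationary. One root seed expands deterministically into independent
#' per-channel streams.
#'
#' @param model a [channel_model()].
#' @param voltage command voltage, mV.
#' @param duration path length, s (> 0).
#' @param seed integer root seed; identical seeds give identical paths.
#' @param init_state optional starting state (label or index) applied to
#'   every channel; by default each channel starts from the stationary
#'   distribution at `voltage`, making finite windows stationary.
#' @return An [ideal_trace()] whose levels range over 0..N*max(level), with
#'   attributes `voltage`, `seed`, `model`, `n_channels` and `channels`
#'   (the per-channel paths, for ground-truth comparisons).
#' @examples
#' m <- two_state_model(100, 100)
#' path <- simulate_gating(m, voltage = 0, duration = 1, seed = 1)
#' time_at_levels(path)
#' @export
simulate_gating <- function(model, voltage, duration, seed = NULL,
                            init_state = NULL) {
  stopifnot(inherits(model, "channel_model"))
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0")
  q <- generator_at(model, voltage)
  if (any(!is.finite(q))) stop("non-finite rates at this voltage")
  if (nrow(q) > 1 && any(diag(q) == 0))
    stop("model has an absorbing state with no escape at ", voltage, " mV")
  if (!is.null(init_state)) {
    if (is.character(init_state)) init_state <- match(init_state, model$states)
    if (is.na(init_state) || init_state < 1 || init_state > nrow(q))
      stop("unknown 'init_state'")
  }
  pi0 <- stationary_dist(model, voltage)
  n <- model$n_channels
  seeds <- expand_seed(if (is.null(seed)) NULL else seed, n + 1L)

  paths <- vector("list", n)
  for (ch in seq_len(n)) {
    paths[[ch]] <- with_seed(if (is.null(seed)) NULL else seeds[ch], {
      s0 <- if (is.null(init_state))
        sample.int(length(pi0), 1, prob = pi0) else init_state
      sample_path(q, s0, duration)
    })
  }

  # merge per-channel level steps into one aggregate level sequence
  lev <- model$levels
  breaks <- sort(unique(c(0, unlist(lapply(paths, `[[`, "start_s")))))
  breaks <- breaks[breaks < duration]
  agg <- integer(length(breaks))
  for (ch in seq_len(n)) {
    p <- paths[[ch]]
    idx <- findInterval(breaks, p$start_s)
    agg <- agg + lev[p$state[idx]]
  }
  durs <- diff(c(breaks, duration))
  keep <- durs > 0
  ideal_trace(agg[keep], durs[keep], voltage = voltage, seed = seed,
              model = model$name, n_channels = n,
              channels = lapply(paths, function(p) {
                data.frame(start_s = p$start_s, level = lev[p$state])
              }))
}

# 4-pole Bessel low-pass (bilinear transform of the analog prototype with
# prewarped -3 dB cutoff); start-up transient suppressed by padding with
# the first sample.
bessel4_lowpass <- function(x, cutoff_hz, sampling_rate) {
  # poles of the reversed Bessel polynomial theta_4(s)
  p <- polyroot(c(105, 105, 45, 10, 1))
  hmag <- function(w) abs(prod(-p) / prod(1i * w - p))
  w3db <- stats::uniroot(function(w) hmag(w) - 1 / sqrt(2),
                         c(0.5, 5), tol = 1e-12)$root
  warp <- 2 * sampling_rate * tan(pi * cutoff_hz / sampling_rate)
  pa <- p / w3db * warp
  T <- 1 / sampling_rate
  pz <- (1 + pa * T / 2) / (1 - pa * T / 2)     # bilinear transform
  a <- Re(signal::poly(pz))
  b <- Re(signal::poly(rep(-1 + 0i, 4)))
  b <- b * sum(a) / sum(b)                       # unity DC gain
  npad <- min(length(x), 256L)
  y <- signal::filter(b, a, c(rep(x[1], npad), x))
  as.numeric(y[-seq_len(npad)])
}

#' Render an idealized gating path as a digitized current trace
#'
#' Converts aggregate conductance levels into current by Ohm's law,
#' \eqn{i = G (V - V_{rev}) / 10^3} (G in pS, V in mV, i in pA), samples it
#' on the acquisition time base, adds white Gaussian baseline noise, and
#' applies the low-pass filter stage. With `noise_sd = 0` and filtering
#' disabled the samples equal `level * i_unitary` exactly. The digital
#' filter is only applied when the cutoff is below 0.49 of the sampling
#' rate; at the Nyquist-limit default (5 kHz cutoff, 10 kHz sampling) the
#' analog filter precedes digitization and the noise level is already the
#' post-filter floor.
#'
#' @param ideal an [ideal_trace()] from [simulate_gating()].
#' @param model the generating [channel_model()] (supplies G and V_rev).
#' @param voltage command voltage, mV.
#' @param acq an [acquisition_spec()].
#' @return A [pq_trace()] of `round(duration * sampling_rate)` samples.
#' @export
render_current <- function(ideal, model, voltage, acq = acquisition_spec()) {
  stopifnot(inherits(ideal, "ideal_trace"), inherits(model, "channel_model"),
            inherits(acq, "acquisition_spec"))
  if (max(ideal$level) > model$n_channels * max(model$levels))
    stop("idealized levels exceed what the model can produce")
  fs <- acq$sampling_rate
  n <- round(total_duration(ideal) * fs)
  t <- (seq_len(n) - 1) / fs
  i_unit <- unitary_current(model, voltage)
  x <- level_at(ideal, t) * i_unit
  if (acq$noise_sd > 0)
    x <- x + with_seed(acq$seed, stats::rnorm(n, 0, acq$noise_sd))
  if (acq$filter_cutoff > 0 && acq$filter_cutoff < 0.49 * fs)
    x <- bessel4_lowpass(x, acq$filter_cutoff, fs)
  pq_trace(x, fs, voltage = voltage, filter_cutoff = acq$filter_cutoff,
           seed = if (is.null(acq$seed)) NA_integer_ else acq$seed,
           model = model$name)
}

#' Unitary current of a channel model at a voltage
#'
#' @inheritParams render_current
#' @return Single-channel current, pA: `G * (V - V_rev) / 1000`.
#' @export
unitary_current <- function(model, voltage) {
  model$conductance_pS * (voltage - model$reversal_mV) / 1000
}

#' Simulate a patch recording (gating + rendering) in one call
#'
#' @inheritParams simulate_gating
#' @param acq an [acquisition_spec()]; its noise stream is seeded from the
#'   root `seed` so a single integer reproduces the whole sweep.
#' @return A [pq_trace()], with the generating path in attribute `ideal`.
#' @export
simulate_patch <- function(model, voltage, duration, seed = NULL,
                           acq = acquisition_spec()) {
  seeds <- expand_seed(seed, 2L)
  ideal <- simulate_gating(model, voltage, duration,
                           seed = if (is.null(seed)) NULL else seeds[1])
  if (is.null(acq$seed) && !is.null(seed)) acq$seed <- seeds[2]
  tr <- render_current(ideal, model, voltage, acq)
  attr(tr, "ideal") <- ideal
  tr
}

#' Simulate whole-cell macroscopic currents under a voltage protocol
#'
#' Generates the summed current of a large channel population. For step
#' protocols each sweep follows the monoexponential activation
#' \eqn{I(V, t) = I_{ss}(V) (1 - e^{-t/\tau})} plus baseline noise, where
#' the steady-state current \eqn{I_{ss}(V)} follows an outwardly rectifying
#' curve: a Boltzmann activation term times the ohmic driving force,
#' scaled so that the current at the reference voltage equals
#' `max_density_pA_pF * capacitance` exactly. For ramp protocols the
#' current tracks \eqn{I_{ss}(V(t))} quasi-statically.
#'
#' @param protocol a [voltage_protocol()].
#' @param density_params list with elements `max_density_pA_pF` (peak
#'   current density at the reference voltage), `v_ref` (reference voltage,
#'   mV; default 180), `v_rev` (reversal potential, mV; default 0),
#'   `v_half`, `slope_mV` (Boltzmann midpoint and slope of the
#'   rectification curve; defaults 60 and 30 mV), `tau_ms` (activation
#'   time constant; default 10 ms, > 0).
#' @param capacitance membrane capacitance, pF (> 0).
#' @param acq an [acquisition_spec()].
#' @param seed integer seed for the noise streams.
#' @return For steps, a `step_family`; for ramps, a single [pq_trace()]
#'   with per-sample command voltage.
#' @export
simulate_whole_cell <- function(protocol, density_params, capacitance,
                                acq = acquisition_spec(), seed = NULL) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (!is.numeric(capacitance) || capacitance <= 0)
    stop("'capacitance' must be > 0")
  dp <- utils::modifyList(list(v_ref = 180, v_rev = 0, v_half = 60,
                               slope_mV = 30, tau_ms = 10), density_params)
  if (is.null(dp$max_density_pA_pF))
    stop("'density_params' must supply max_density_pA_pF")
  if (dp$tau_ms <= 0) stop("activation tau must be > 0")

  shape <- function(v) (v - dp$v_rev) / (1 + exp(-(v - dp$v_half) / dp$slope_mV))
  s_ref <- shape(dp$v_ref)
  if (s_ref == 0) stop("rectification curve vanishes at the reference voltage")
  i_ss <- function(v) dp$max_density_pA_pF * capacitance * shape(v) / s_ref

  fs <- acq$sampling_rate
  add_noise <- function(x, s) {
    if (acq$noise_sd > 0) x + with_seed(s, stats::rnorm(length(x), 0, acq$noise_sd))
    else x
  }

  if (protocol$kind == "step") {
    volts <- protocol_voltages(protocol)
    seeds <- expand_seed(seed, length(volts))
    n <- round(protocol$step_ms / 1000 * fs)
    t_ms <- (seq_len(n) - 1) / fs * 1000
    traces <- lapply(seq_along(volts), function(k) {
      y <- i_ss(volts[k]) * (1 - exp(-t_ms / dp$tau_ms))
      y <- add_noise(y, if (is.null(seed)) NULL else seeds[k])
      pq_trace(y, fs, voltage = volts[k], capacitance = capacitance,
               filter_cutoff = acq$filter_cutoff,
               seed = if (is.null(seed)) NA_integer_ else seed,
               model = "whole-cell")
    })
    step_family(traces, capacitance = capacitance, protocol = protocol)
  } else if (protocol$kind == "ramp") {
    n <- round(protocol$duration_ms / 1000 * fs)
    v <- seq(protocol$start_mV, protocol$stop_mV, length.out = n)
    y <- add_noise(i_ss(v), seed)
    pq_trace(y, fs, voltage = v, capacitance = capacitance,
             filter_cutoff = acq$filter_cutoff,
             seed = if (is.null(seed)) NA_integer_ else seed,
             model = "whole-cell")
  } else stop("hold protocols carry no activation waveform to simulate")
}
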