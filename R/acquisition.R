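#' Acquisition settings of a recording
#'
#' Bundles the digitization and conditioning parameters of a patch-clamp
#' recording: sample rate, low-pass cutoff of the amplifier filter, the
#' standard deviation of the additive baseline noise, and an optional seed
#' for reproducible noise. Defaults match a common amplifier configuration:
#' 10 kHz digitization after a 5 kHz low-pass filter.
#'
#' The digital low-pass stage is only meaningful when the cutoff lies below
#' the Nyquist frequency; at `filter_cutoff >= 0.49 * sampling_rate` (as with
#' the 5 kHz / 10 kHz default, where the analog filter acts before
#' digitization) the rendered noise is treated as the post-filter noise
#' floor and no digital filtering is applied.
#'
#' @param sampling_rate digitization rate, Hz.
#' @param filter_cutoff low-pass (-3 dB) cutoff, Hz; must satisfy
#'   `sampling_rate >= 2 * filter_cutoff`. Use 0 or `NA` to disable.
#' @param noise_sd baseline noise standard deviation, pA (>= 0).
#' @param seed optional integer seed for the noise stream.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_rate = 10000, filter_cutoff = 5000,
                             noise_sd = 0.3, seed = NULL) {
  stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
  if (is.null(filter_cutoff) || is.na(filter_cutoff)) filter_cutoff <- 0
  if (filter_cutoff < 0) stop("'filter_cutoff' must be >= 0")
  if (filter_cutoff > 0 && sampling_rate < 2 * filter_cutoff)
    stop("sampling_rate must be at least twice the filter cutoff")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 noise_sd = noise_sd, seed = seed),
            class = "acquisition_spec")
}

#' Command-voltage protocols
#'
#' Describes the voltage-clamp command waveform. Step protocols hold at
#' `holding_mV`, step through `seq(start_mV, stop_mV, by = increment_mV)`
#' for `step_ms` each and return via a tail pulse; ramp protocols sweep
#' linearly from `start_mV` to `stop_mV` over `duration_ms`. Defaults are a
#' step family from -100 to +180 mV in 20 mV increments (150 ms steps,
#' 0 mV holding, -80 mV tail) and a -100 to +180 mV, 500 ms ramp.
#'
#' @param kind one of `"step"`, `"ramp"`, `"hold"`.
#' @param start_mV,stop_mV first and last command voltage, mV.
#' @param increment_mV step increment, mV; must divide `stop_mV - start_mV`.
#' @param step_ms duration of each step, ms.
#' @param holding_mV,tail_mV holding and tail-pulse potentials, mV (steps).
#' @param duration_ms ramp or hold duration, ms.
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(kind = c("step", "ramp", "hold"),
                             start_mV = -100, stop_mV = 180,
                             increment_mV = 20, step_ms = 150,
                             holding_mV = 0, tail_mV = -80,
                             duration_ms = 500) {
  kind <- match.arg(kind)
  if (kind == "step") {
    if (increment_mV == 0 ||
        abs((stop_mV - start_mV) / increment_mV -
            round((stop_mV - start_mV) / increment_mV)) > 1e-9)
      stop("'increment_mV' must evenly divide stop_mV - start_mV")
    if (step_ms <= 0) stop("step duration must be > 0")
  } else {
    if (duration_ms <= 0) stop("duration must be > 0")
  }
  structure(list(kind = kind, start_mV = start_mV, stop_mV = stop_mV,
                 increment_mV = increment_mV, step_ms = step_ms,
                 holding_mV = holding_mV, tail_mV = tail_mV,
                 duration_ms = duration_ms),
            class = "voltage_protocol")
}

#' Command voltages of a step protocol
#'
#' @param protocol a step `voltage_protocol`.
#' @return Numeric vector of step voltages, mV.
#' @export
protocol_voltages <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (protocol$kind != "step")
    stop("protocol_voltages() is defined for step protocols")
  seq(protocol$start_mV, protocol$stop_mV, by = protocol$increment_mV)
}
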