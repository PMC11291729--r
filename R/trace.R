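#' Sampled current trace
#'
#' Container for one digitized sweep: current samples in pA on a uniform
#' time base, with the command voltage (a scalar for holds and steps, a
#' per-sample vector for ramps) and acquisition metadata.
#'
#' @param samples numeric vector of current samples, pA; must be finite.
#' @param sampling_rate Hz.
#' @param voltage command voltage, mV: scalar, or one value per sample.
#' @param capacitance membrane capacitance, pF (whole-cell sweeps).
#' @param filter_cutoff low-pass cutoff applied to the data, Hz.
#' @param seed seed used to generate the sweep, if simulated.
#' @param model label of the generating model, if simulated.
#' @return An object of class `pq_trace`.
#' @export
pq_trace <- function(samples, sampling_rate, voltage = NA_real_,
                     capacitance = NA_real_, filter_cutoff = NA_real_,
                     seed = NA_integer_, model = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("trace has no samples")
  if (any(!is.finite(samples))) stop("trace samples must be finite")
  if (!(length(voltage) %in% c(1L, length(samples))))
    stop("'voltage' must be scalar or one value per sample")
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 voltage = voltage,
                 capacitance = capacitance,
                 filter_cutoff = filter_cutoff,
                 seed = seed, model = model),
            class = "pq_trace")
}

#' @export
print.pq_trace <- function(x, ...) {
  v <- if (length(x$voltage) > 1) {
    sprintf("ramp %g to %g mV", x$voltage[1], x$voltage[length(x$voltage)])
  } else sprintf("%g mV", x$voltage)
  cat(sprintf("Current trace: %d samples at %g Hz (%.4g s), %s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, v))
  invisible(x)
}

#' Sample times of a trace
#' @param trace a `pq_trace`.
#' @return Time of each sample from sweep start, s.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Duration of a trace, s
#' @param trace a `pq_trace`.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate
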