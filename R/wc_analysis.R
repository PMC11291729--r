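# Whole-cell analysis: per-step maximum currents, current density,
# monoexponential activation time constant, and ramp reversal potential.

#' A family of step-protocol sweeps from one cell
#'
#' @param traces list of [pq_trace()]s, one per command voltage, sharing a
#'   sampling rate.
#' @param capacitance membrane capacitance, pF (> 0).
#' @param protocol the generating step [voltage_protocol()].
#' @return An object of class `step_family`.
#' @export
step_family <- function(traces, capacitance, protocol = voltage_protocol()) {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, TRUE, "pq_trace")))
  fs <- vapply(traces, `[[`, numeric(1), "sampling_rate")
  if (length(unique(fs)) != 1)
    stop("all sweeps in a family must share one sampling rate")
  if (!is.numeric(capacitance) || capacitance <= 0)
    stop("'capacitance' must be > 0")
  v <- vapply(traces, function(tr) tr$voltage[1], numeric(1))
  names(traces) <- sprintf("%+g mV", v)
  structure(list(traces = traces, voltages = v,
                 capacitance = capacitance, protocol = protocol),
            class = "step_family")
}

#' @export
print.step_family <- function(x, ...) {
  cat(sprintf("Step family: %d sweeps (%g to %g mV), Cm = %g pF\n",
              length(x$traces), min(x$voltages), max(x$voltages),
              x$capacitance))
  invisible(x)
}

#' Maximum current per voltage step
#'
#' For each sweep, the signed extremum of the current within the step
#' window: the sample of largest absolute value, so outward steps report
#' their maximum and inward steps their minimum. The first `blank_ms` of
#' each step are excluded to skip the capacitive transient.
#'
#' @param family a [step_family()].
#' @param blank_ms initial blanking interval, ms (default 2).
#' @return Data frame with columns `voltage` (mV) and `i_max` (pA). Steps
#'   expected from the protocol but missing from the family are reported
#'   in attribute `missing_voltages`.
#' @export
max_current_per_step <- function(family, blank_ms = 2) {
  stopifnot(inherits(family, "step_family"))
  imax <- vapply(family$traces, function(tr) {
    n0 <- floor(blank_ms / 1000 * tr$sampling_rate) + 1L
    if (n0 > length(tr$samples))
      stop("blanking interval longer than the sweep")
    x <- tr$samples[n0:length(tr$samples)]
    x[which.max(abs(x))]
  }, numeric(1))
  out <- data.frame(voltage = family$voltages, i_max = unname(imax))
  out <- out[order(out$voltage), ]
  rownames(out) <- NULL
  want <- tryCatch(protocol_voltages(family$protocol), error = function(e) NULL)
  miss <- setdiff(want, out$voltage)
  if (length(miss)) {
    warning("missing voltage steps: ", paste(miss, collapse = ", "))
    attr(out, "missing_voltages") <- miss
  }
  out
}

#' Current density
#'
#' Normalizes current to cell size: I / Cm in pA/pF, sign preserved.
#'
#' @param I current, pA (vectorized).
#' @param capacitance membrane capacitance, pF (> 0).
#' @return Current density, pA/pF.
#' @export
current_density <- function(I, capacitance) {
  if (!is.numeric(capacitance) || length(capacitance) != 1 ||
      !is.finite(capacitance) || capacitance <= 0)
    stop("'capacitance' must be a single positive number")
  I / capacitance
}

#' Fit the activation time constant of a step current
#'
#' Least-squares fit of the monoexponential
#' \deqn{Y(t) = Y_0 + A e^{-t/\tau}}
#' to the current within the fit window (t measured from the window
#' start), returning the time constant in ms. For an activating
#' (relaxing-upward) current, A is negative and Y0 is the steady-state
#' level. The fit is invariant to vertical offsets and to an overall sign
#' flip of the current.
#'
#' @param trace a [pq_trace()].
#' @param window `c(t0, t1)` fit window in seconds; default from `blank_ms`
#'   after sweep start to the end of the sweep.
#' @param blank_ms default window start when `window` is not given, ms.
#' @return An object of class `activation_fit`: `Y0` (pA), `A` (pA),
#'   `tau_ms`, `converged`, `flags` (character vector, e.g.
#'   `"amplitude-degenerate"` for a flat trace where tau is
#'   unidentifiable, or `"tau-at-bound"`), `rss`, `window`, `n`.
#' @examples
#' t_ms <- seq(0, 1, by = 0.1)
#' tr <- pq_trace(2798 * (1 - exp(-t_ms / 0.06)), 10000, voltage = 180)
#' fit_activation_tau(tr, window = c(0, 1e-3))
#' @export
fit_activation_tau <- function(trace, window = NULL, blank_ms = 2) {
  stopifnot(inherits(trace, "pq_trace"))
  tt <- trace_times(trace)
  if (is.null(window)) window <- c(blank_ms / 1000, trace_duration(trace))
  keep <- tt >= window[1] - 1e-12 & tt <= window[2] + 1e-12
  if (sum(keep) < 10)
    stop("fit window contains ", sum(keep), " samples; need >= 10")
  t_ms <- (tt[keep] - tt[keep][1]) * 1000
  y <- trace$samples[keep]
  dt_ms <- 1000 / trace$sampling_rate
  span <- max(t_ms)

  flags <- character(0)
  if (stats::sd(y) < max(1e-12, 1e-9 * max(abs(y), 1))) {
    return(structure(list(Y0 = mean(y), A = 0, tau_ms = NA_real_,
                          converged = FALSE,
                          flags = "amplitude-degenerate",
                          rss = 0, window = window, n = length(y)),
                     class = "activation_fit"))
  }

  n_tail <- max(5L, length(y) %/% 10L)
  y0_0 <- mean(y[(length(y) - n_tail + 1):length(y)])
  a_0 <- y[1] - y0_0
  # crude tau from the time the relaxation falls to 1/e of its span
  dy <- abs(y - y0_0)
  k <- which(dy <= abs(a_0) / exp(1))[1]
  tau_0 <- if (!is.na(k) && k > 1) t_ms[k] else span / 5
  tau_0 <- min(max(tau_0, dt_ms / 10), span * 10)

  lower <- c(-Inf, -Inf, dt_ms / 100)
  upper <- c(Inf, Inf, span * 100)
  fit <- minpack.lm::nls.lm(
    par = c(y0_0, a_0, tau_0), lower = lower, upper = upper,
    fn = function(p) y - (p[1] + p[2] * exp(-t_ms / p[3])),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  tau <- fit$par[3]
  if (tau <= lower[3] * (1 + 1e-6) || tau >= upper[3] * (1 - 1e-6))
    flags <- c(flags, "tau-at-bound")
  converged <- fit$info %in% 1:3 && !("tau-at-bound" %in% flags)
  if (!fit$info %in% 1:3) flags <- c(flags, paste0("optimizer: ", fit$message))
  structure(list(Y0 = fit$par[1], A = fit$par[2], tau_ms = tau,
                 converged = converged, flags = flags,
                 rss = sum(fit$fvec^2), window = window, n = length(y)),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("Activation fit: tau = %.4g ms, Y0 = %.4g pA, A = %.4g pA (%s)\n",
              x$tau_ms, x$Y0, x$A,
              if (x$converged) "converged"
              else paste(c("not converged", x$flags), collapse = "; ")))
  invisible(x)
}

#' Reversal potential from a ramp sweep
#'
#' Builds the I-V relation of a voltage-ramp sweep (per-sample command
#' voltage required), smooths it with a boxcar over voltage (default 1 mV
#' wide), and linearly interpolates the zero-current crossing. If the
#' relation crosses zero more than once the crossing nearest 0 mV is
#' returned, flagged with attribute `n_crossings`.
#'
#' @param ramp a [pq_trace()] with one command voltage per sample.
#' @param smooth_mV boxcar width of the I-V smoothing, mV; 0 disables.
#' @return Reversal potential, mV. If the current does not cross zero in
#'   the swept range, `NA` with attribute `reason = "out of range"`.
#' @export
reversal_potential <- function(ramp, smooth_mV = 1) {
  stopifnot(inherits(ramp, "pq_trace"))
  if (length(ramp$voltage) != length(ramp$samples))
    stop("ramp trace must carry one command voltage per sample")
  ord <- order(ramp$voltage)
  v <- ramp$voltage[ord]; i <- ramp$samples[ord]
  if (smooth_mV > 0) {
    dv <- mean(diff(v))
    k <- max(1L, round(smooth_mV / dv))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1) {
      sm <- as.numeric(stats::filter(i, rep(1 / k, k), sides = 2))
      i[!is.na(sm)] <- sm[!is.na(sm)]
    }
  }
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(i == 0)
  vr <- c(v[exact],
          vapply(cross, function(k) {
            v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
          }, numeric(1)))
  vr <- unique(vr)
  if (length(vr) == 0)
    return(structure(NA_real_, reason = "out of range"))
  out <- vr[which.min(abs(vr))]
  if (length(vr) > 1) attr(out, "n_crossings") <- length(vr)
  out
}
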