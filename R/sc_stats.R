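# Single-channel statistics: open probability (single- and multi-channel),
# level-weighted open time, NPo, normalization across voltages, and slope
# conductance from the unitary current-voltage relation.

open_prob_result <- function(voltage, Popen, NPo, To, Tc, T, N, window) {
  structure(list(voltage = voltage, Popen = Popen, NPo = NPo,
                 To = To, Tc = Tc, T = T, N = N, window = window),
            class = "open_prob_result")
}

#' @export
print.open_prob_result <- function(x, ...) {
  cat(sprintf(
    "Open probability at %g mV (N = %d, window %g + %g s):\n", x$voltage,
    x$N, x$window[1], x$window[2]))
  cat(sprintf("  Popen = %.4g   NPo = %.4g   To = %.4g s   Tc = %.4g s\n",
              x$Popen, x$NPo, x$To, x$Tc))
  invisible(x)
}

#' Single-channel open probability
#'
#' Popen = To / T, where To is the total time the channel spends open
#' (aggregate level >= 1) and T is the observation window. By convention a
#' fixed-length window (default 10 s) is taken from each per-voltage
#' recording.
#'
#' @param ideal an [ideal_trace()].
#' @param window_s observation window length, s; must fit inside the trace.
#' @param start_s window start, s (default 0).
#' @return An `open_prob_result` with fields `Popen`, `NPo`, `To`, `Tc`,
#'   `T`, `N` (= 1), `voltage`, `window`.
#' @export
popen <- function(ideal, window_s = 10, start_s = 0) {
  stopifnot(inherits(ideal, "ideal_trace"))
  w <- clip_ideal(ideal, start_s, window_s)
  to <- sum(w$duration_s[w$level >= 1])
  open_prob_result(attr(ideal, "voltage"), Popen = to / window_s,
                   NPo = npo(ideal, window_s, start_s),
                   To = to, Tc = window_s - to, T = window_s, N = 1L,
                   window = c(start_s, window_s))
}

#' Open probability of a multi-channel patch
#'
#' For a patch holding N identical channels, Popen = To / (N T) with the
#' level-weighted open time To of [level_weighted_open_time()], so that
#' simultaneous openings count once per open channel. With N = 1 this
#' reduces exactly to [popen()].
#'
#' @inheritParams popen
#' @param N number of channels in the patch; must be at least the maximum
#'   observed aggregate level.
#' @return An `open_prob_result` (fields as in [popen()], `N` as given,
#'   `Tc` = time with every channel closed).
#' @export
popen_multi <- function(ideal, N, window_s = 10, start_s = 0) {
  stopifnot(inherits(ideal, "ideal_trace"))
  N <- as.integer(N)
  maxlev <- max(ideal$level)
  if (N < maxlev)
    stop(sprintf("N = %d is smaller than the maximum observed level %d",
                 N, maxlev))
  w <- clip_ideal(ideal, start_s, window_s)
  to <- level_weighted_open_time(w)
  tc <- sum(w$duration_s[w$level == 0])
  open_prob_result(attr(ideal, "voltage"), Popen = to / (N * window_s),
                   NPo = npo(ideal, window_s, start_s),
                   To = to, Tc = tc, T = window_s, N = N,
                   window = c(start_s, window_s))
}

#' Level-weighted total open time
#'
#' To = sum over levels L of L times the time spent at aggregate level L:
#' a dwell at level 2 (two channels open, or a doubly conducting level)
#' contributes twice its duration.
#'
#' @param ideal an [ideal_trace()].
#' @return Open time in seconds (0 for an always-closed trace).
#' @export
level_weighted_open_time <- function(ideal) {
  stopifnot(inherits(ideal, "ideal_trace"))
  sum(ideal$level * ideal$duration_s)
}

#' Absolute open probability NPo
#'
#' NPo = To / (To + Tc), with the level-weighted open time To of
#' [level_weighted_open_time()] and Tc the total time at aggregate level 0
#' (all channels closed). The formula is applied literally: when
#' multi-level openings occur, To is level-weighted while Tc is clock
#' time, so the denominator need not equal the window length. For a
#' strict time-fraction alternative set `per_sample = TRUE`, which returns
#' the unweighted fraction of time any channel is open.
#'
#' @inheritParams popen
#' @param per_sample if `TRUE`, return the fraction of the window with
#'   aggregate level >= 1 instead of the literal level-weighted statistic.
#' @return NPo, dimensionless (equal to Popen when the maximum level is 1).
#' @export
npo <- function(ideal, window_s = 10, start_s = 0, per_sample = FALSE) {
  stopifnot(inherits(ideal, "ideal_trace"))
  if (window_s <= 0) stop("empty observation window")
  w <- clip_ideal(ideal, start_s, window_s)
  if (per_sample) return(sum(w$duration_s[w$level >= 1]) / window_s)
  to <- level_weighted_open_time(w)
  tc <- sum(w$duration_s[w$level == 0])
  if (to + tc == 0) return(0)
  to / (to + tc)
}

#' Normalize an open-probability series to its maximum
#'
#' Divides each per-voltage Popen by the maximum of the series, so the
#' most-activating voltage maps to 1.
#'
#' @param results list of `open_prob_result`s, or a numeric Popen vector.
#' @return Data frame with columns `voltage`, `Popen`, `Popen_norm`. An
#'   all-zero series returns zeros with attribute `all_zero = TRUE`
#'   instead of 0/0.
#' @export
normalize_popen <- function(results) {
  if (is.numeric(results)) {
    v <- rep(NA_real_, length(results)); p <- as.numeric(results)
  } else {
    stopifnot(length(results) >= 1,
              all(vapply(results, inherits, TRUE, "open_prob_result")))
    v <- vapply(results, `[[`, numeric(1), "voltage")
    p <- vapply(results, `[[`, numeric(1), "Popen")
  }
  if (length(p) < 1) stop("empty open-probability series")
  mx <- max(p)
  out <- data.frame(voltage = v, Popen = p,
                    Popen_norm = if (mx > 0) p / mx else rep(0, length(p)))
  if (mx <= 0) attr(out, "all_zero") <- TRUE
  out
}

#' Unitary current-voltage relation
#'
#' @param voltage command voltages, mV.
#' @param current unitary current amplitudes, pA (same length).
#' @param n,se optional per-point replicate counts and standard errors.
#' @return An object of class `iv_curve` (a data frame).
#' @export
iv_curve <- function(voltage, current, n = NULL, se = NULL) {
  stopifnot(length(voltage) == length(current))
  keep <- is.finite(current)
  out <- data.frame(voltage = voltage[keep], current = current[keep])
  if (!is.null(n)) out$n <- n[keep]
  if (!is.null(se)) out$se <- se[keep]
  structure(out, class = c("iv_curve", "data.frame"))
}

#' Slope conductance from an I-V relation
#'
#' Ordinary (unweighted) least-squares fit of unitary current (pA) against
#' voltage (mV); the slope in pA/mV (= nS) times 1000 is the conductance
#' in pS. A voltage range restricts the fit to one limb of the relation,
#' for channels whose inward and outward conductances differ.
#'
#' @param iv an [iv_curve()].
#' @param range optional `c(min_mV, max_mV)` restricting the fitted points.
#' @return An object of class `conductance_fit`: `conductance_pS`,
#'   `intercept_pA`, `r_squared`, `range`, `n_points`, and the underlying
#'   `lm` fit.
#' @export
conductance <- function(iv, range = NULL) {
  stopifnot(inherits(iv, "iv_curve"))
  d <- as.data.frame(iv)
  if (!is.null(range)) d <- d[d$voltage >= range[1] & d$voltage <= range[2], ]
  if (length(unique(d$voltage)) < 2)
    stop("conductance fit needs >= 2 distinct voltages",
         if (!is.null(range)) " in the requested range" else "")
  fit <- stats::lm(current ~ voltage, data = d)
  sl <- unname(stats::coef(fit)["voltage"])
  if (!is.finite(sl)) stop("rank-deficient I-V fit")
  tss <- sum((d$current - mean(d$current))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(conductance_pS = sl * 1000,
                 intercept_pA = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2,
                 range = if (is.null(range)) range(d$voltage) else range,
                 n_points = nrow(d), fit = fit),
            class = "conductance_fit")
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat(sprintf(
    "Slope conductance: %.4g pS (intercept %.3g pA, R^2 = %.4f, %d points in %g..%g mV)\n",
    x$conductance_pS, x$intercept_pA, x$r_squared, x$n_points,
    x$range[1], x$range[2]))
  invisible(x)
}
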