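#' Idealized (piecewise-constant) channel activity
#'
#' An idealized trace is the event-list representation of channel activity:
#' a sequence of dwells, each with an integer aggregate conductance level
#' and a duration in seconds. Consecutive dwells always differ in level and
#' durations sum exactly to the total duration.
#'
#' @param level integer vector of aggregate conductance levels (>= 0).
#' @param duration numeric vector of dwell durations, s (> 0).
#' @param voltage command voltage of the originating sweep, mV (optional).
#' @param ... further metadata stored as attributes (e.g. `seed`, `model`).
#' @return An object of class `ideal_trace`: a data frame with columns
#'   `level`, `start_s`, `duration_s`.
#' @export
ideal_trace <- function(level, duration, voltage = NA_real_, ...) {
  level <- as.integer(level)
  duration <- as.numeric(duration)
  stopifnot(length(level) == length(duration), length(level) >= 1)
  if (any(duration <= 0)) stop("dwell durations must be > 0")
  if (any(level < 0)) stop("levels must be >= 0")
  # collapse any consecutive equal levels
  if (length(level) > 1) {
    same <- c(FALSE, level[-1] == level[-length(level)])
    if (any(same)) {
      grp <- cumsum(!same)
      duration <- as.numeric(tapply(duration, grp, sum))
      level <- level[!same]
    }
  }
  out <- data.frame(level = level,
                    start_s = cumsum(c(0, duration[-length(duration)])),
                    duration_s = duration)
  structure(out, class = c("ideal_trace", "data.frame"),
            total_s = sum(duration), voltage = voltage, ...)
}

#' @export
print.ideal_trace <- function(x, ...) {
  cat(sprintf("Idealized trace: %d dwells over %.6g s (max level %d)\n",
              nrow(x), attr(x, "total_s"), max(x$level)))
  NextMethod()
}

#' Total duration of an idealized trace, s
#' @param ideal an `ideal_trace`.
#' @export
total_duration <- function(ideal) attr(ideal, "total_s")

#' Time spent at each aggregate level
#'
#' @param ideal an `ideal_trace`.
#' @return Named numeric vector: seconds at each observed level.
#' @export
time_at_levels <- function(ideal) {
  stopifnot(inherits(ideal, "ideal_trace"))
  tapply(ideal$duration_s, ideal$level, sum)
}

#' Restrict an idealized trace to a time window
#'
#' Dwells are clipped at the window edges; durations of the clipped trace
#' sum exactly to the window length.
#'
#' @param ideal an `ideal_trace`.
#' @param start_s window start, s.
#' @param length_s window length, s.
#' @return An `ideal_trace` covering exactly `[start_s, start_s + length_s)`.
#' @export
clip_ideal <- function(ideal, start_s, length_s) {
  stopifnot(inherits(ideal, "ideal_trace"), length_s > 0, start_s >= 0)
  total <- attr(ideal, "total_s")
  if (start_s + length_s > total + 1e-12)
    stop(sprintf("window [%g, %g] s exceeds trace duration %g s",
                 start_s, start_s + length_s, total))
  end_s <- start_s + length_s
  ev_end <- ideal$start_s + ideal$duration_s
  keep <- ev_end > start_s & ideal$start_s < end_s
  lv <- ideal$level[keep]
  s <- pmax(ideal$start_s[keep], start_s)
  e <- pmin(ev_end[keep], end_s)
  ideal_trace(lv, e - s, voltage = attr(ideal, "voltage"))
}

#' Aggregate level at given times
#'
#' @param ideal an `ideal_trace`.
#' @param t numeric vector of times, s, within the trace.
#' @return Integer levels at the requested times.
#' @export
level_at <- function(ideal, t) {
  idx <- findInterval(t, ideal$start_s, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  ideal$level[idx]
}
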