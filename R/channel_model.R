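#' Define a kinetic model of an ion channel
#'
#' A channel model is a continuous-time Markov chain over a small set of
#' conformational states, each carrying an integer conductance level
#' (0 = closed, 1 = open; sub- or supra-conductance states may use other
#' levels), together with the unitary conductance and reversal potential
#' that turn gating into current, and the number of identical, independent
#' channels in the patch.
#'
#' Transition rates may depend on membrane voltage through a per-edge
#' exponential factor, \eqn{k(V) = k_0 \exp(V / V_s)}: `v_slope[i, j]` is the
#' e-fold voltage \eqn{V_s} in mV for the i-to-j transition, with `Inf`
#' (the default) meaning voltage-independent.
#'
#' @param states character vector of state labels.
#' @param levels integer conductance level per state, same length as
#'   `states`; at least one state must have level 0.
#' @param rates square matrix of transition rates at 0 mV, in 1/s;
#'   `rates[i, j]` is the rate from state i to state j. The diagonal is
#'   ignored (recomputed so generator rows sum to zero).
#' @param v_slope optional matrix of e-fold voltages (mV) matching `rates`;
#'   entries of `Inf` give voltage-independent rates.
#' @param conductance_pS unitary (single-channel) conductance, pS; > 0.
#' @param reversal_mV reversal potential, mV.
#' @param n_channels number of identical channels in the patch (N >= 1).
#' @param name optional model label carried into trace provenance.
#'
#' @return An object of class `channel_model`.
#' @seealso [two_state_model()], [simulate_gating()], [render_current()]
#' @examples
#' m <- two_state_model(opening_rate = 50, closing_rate = 50,
#'                      conductance_pS = 96.5)
#' generator_at(m, voltage = 100)
#' @export
channel_model <- function(states, levels, rates, v_slope = NULL,
                          conductance_pS, reversal_mV = 0,
                          n_channels = 1L, name = "channel") {
  n <- length(states)
  stopifnot(n >= 1, length(levels) == n)
  levels <- as.integer(levels)
  if (any(is.na(levels)) || any(levels < 0))
    stop("conductance levels must be non-negative integers")
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(n, n)))
    stop("'rates' must be a ", n, "x", n, " matrix")
  if (any(!is.finite(rates[row(rates) != col(rates)])))
    stop("off-diagonal transition rates must be finite")
  if (any(rates[row(rates) != col(rates)] < 0))
    stop("transition rates must be non-negative")
  if (is.null(v_slope)) v_slope <- matrix(Inf, n, n)
  v_slope <- as.matrix(v_slope)
  if (!all(dim(v_slope) == c(n, n)))
    stop("'v_slope' must match the dimensions of 'rates'")
  if (any(v_slope == 0, na.rm = TRUE))
    stop("'v_slope' entries must be nonzero (use Inf for no voltage dependence)")
  if (!is.numeric(conductance_pS) || length(conductance_pS) != 1 ||
      !is.finite(conductance_pS) || conductance_pS <= 0)
    stop("'conductance_pS' must be a single positive number")
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1)
    stop("'n_channels' must be an integer >= 1")
  diag(rates) <- 0

  m <- structure(list(
    states = as.character(states),
    levels = levels,
    rates = rates,
    v_slope = v_slope,
    conductance_pS = conductance_pS,
    reversal_mV = reversal_mV,
    n_channels = n_channels,
    name = name
  ), class = "channel_model")
  # a multi-state model must allow escape from every state
  if (n > 1 && any(rowSums(rates) == 0))
    stop("model has an absorbing state with no escape: ",
         paste(states[rowSums(rates) == 0], collapse = ", "))
  m
}

#' Two-state closed/open gating model
#'
#' Convenience constructor for the canonical C <-> O scheme with an
#' optionally voltage-dependent opening rate,
#' \eqn{\beta(V) = \beta_0 \exp(V / V_s)}.
#'
#' @param opening_rate C-to-O rate at 0 mV, 1/s.
#' @param closing_rate O-to-C rate, 1/s (voltage-independent).
#' @param opening_v_slope e-fold voltage (mV) of the opening rate;
#'   `Inf` for a voltage-independent chain.
#' @inheritParams channel_model
#' @return A `channel_model` with states `C` (level 0) and `O` (level 1).
#' @export
two_state_model <- function(opening_rate, closing_rate,
                            conductance_pS = 96.5, reversal_mV = 0,
                            n_channels = 1L, opening_v_slope = Inf,
                            name = "two-state") {
  rates <- matrix(c(0, opening_rate,
                    closing_rate, 0), 2, 2, byrow = TRUE)
  vs <- matrix(Inf, 2, 2)
  vs[1, 2] <- opening_v_slope
  channel_model(states = c("C", "O"), levels = c(0L, 1L), rates = rates,
                v_slope = vs, conductance_pS = conductance_pS,
                reversal_mV = reversal_mV, n_channels = n_channels,
                name = name)
}

#' Infinitesimal generator of a channel model at a given voltage
#'
#' Evaluates the voltage-dependent rates and assembles the generator matrix
#' Q, whose rows sum to zero.
#'
#' @param model a `channel_model`.
#' @param voltage membrane potential, mV.
#' @return The generator matrix (1/s), states in model order.
#' @export
generator_at <- function(model, voltage) {
  stopifnot(inherits(model, "channel_model"), is.finite(voltage))
  q <- model$rates * exp(voltage / model$v_slope)
  q[model$rates == 0] <- 0       # 0 * exp(overflow) is still a zero rate
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  q
}

#' Stationary distribution of the gating chain at a voltage
#'
#' Solves pi Q = 0 with sum(pi) = 1 by the standard augmented linear system.
#'
#' @inheritParams generator_at
#' @return Named numeric vector of stationary state probabilities.
#' @export
stationary_dist <- function(model, voltage) {
  q <- generator_at(model, voltage)
  n <- nrow(q)
  if (n == 1) return(stats::setNames(1, model$states))
  a <- cbind(q, 1)                # solve pi %*% [Q | 1] = [0 .. 0 1]
  pi <- drop(solve(tcrossprod(a), a %*% c(rep(0, n), 1)))
  pi <- pmax(pi, 0)
  stats::setNames(pi / sum(pi), model$states)
}

#' @export
print.channel_model <- function(x, ...) {
  cat("Channel model:", x$name, "\n")
  cat("  states:", paste0(x$states, " (L", x$levels, ")", collapse = ", "), "\n")
  cat(sprintf("  G = %g pS, V_rev = %g mV, N = %d channels\n",
              x$conductance_pS, x$reversal_mV, x$n_channels))
  invisible(x)
}
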