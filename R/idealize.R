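# Amplitude-domain analysis: histograms, Gaussian-mixture fits of the
# closed/open current levels, unitary amplitude, and half-amplitude
# threshold idealization.

#' Subtract slow baseline drift from a trace
#'
#' Estimates the baseline as a piecewise-linear curve through per-segment
#' closed-level estimates (the mode of each segment's sample density,
#' which tracks the closed level whenever closures dominate the segment)
#' and subtracts it. Off by default everywhere; intended for records with
#' seal drift before histogramming.
#'
#' @param trace a [pq_trace()].
#' @param n_segments number of equal-length segments defining the
#'   baseline nodes (>= 2).
#' @return A [pq_trace()] with the drift removed; the estimated baseline
#'   is attached as attribute `baseline`.
#' @export
subtract_baseline <- function(trace, n_segments = 10) {
  stopifnot(inherits(trace, "pq_trace"), n_segments >= 2)
  n <- length(trace$samples)
  seg <- pmin(ceiling(seq_len(n) / (n / n_segments)), n_segments)
  centers <- tapply(seq_len(n), seg, function(i) mean(range(i)))
  nodes <- tapply(trace$samples, seg, function(x) {
    d <- stats::density(x, n = 256)
    d$x[which.max(d$y)]
  })
  base <- stats::approx(centers, nodes, xout = seq_len(n), rule = 2)$y
  out <- trace
  out$samples <- trace$samples - base
  attr(out, "baseline") <- base
  out
}

#' All-points amplitude histogram of a current trace
#'
#' Bins every sample of the sweep. The default bin width follows the
#' Freedman-Diaconis rule; bins cover the full data range.
#'
#' @param trace a [pq_trace()].
#' @param bin_width bin width in pA; default Freedman-Diaconis.
#' @return An object of class `amp_hist` with fields `bin_edges` (pA),
#'   `counts`, `mids`, `bin_width`, `voltage`, `n_samples`.
#' @export
amplitude_histogram <- function(trace, bin_width = NULL) {
  stopifnot(inherits(trace, "pq_trace"))
  x <- trace$samples
  if (any(!is.finite(x))) stop("trace contains non-finite samples")
  if (is.null(bin_width)) {
    nb <- grDevices::nclass.FD(x)
    bin_width <- diff(range(x)) / max(nb, 1)
    if (bin_width == 0) bin_width <- 1e-3      # constant trace
  }
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  lo <- floor(min(x) / bin_width) * bin_width
  edges <- seq(lo, max(x) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1)
  structure(list(bin_edges = edges, counts = counts,
                 mids = edges[-length(edges)] + bin_width / 2,
                 bin_width = bin_width,
                 voltage = if (length(trace$voltage) == 1) trace$voltage
                           else NA_real_,
                 n_samples = length(x)),
            class = "amp_hist")
}

#' @export
print.amp_hist <- function(x, ...) {
  cat(sprintf(
    "Amplitude histogram: %d samples in %d bins of %.4g pA (%.4g to %.4g pA)\n",
    x$n_samples, length(x$counts), x$bin_width,
    min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

# Initial guesses for mixture components: the n tallest separated local
# maxima of the lightly smoothed histogram, falling back to spread
# quantiles when fewer peaks are visible.
mixture_init <- function(hist, n_components) {
  y <- as.numeric(stats::filter(hist$counts, rep(1 / 3, 3), sides = 2))
  y[is.na(y)] <- hist$counts[is.na(y)]
  m <- length(y)
  is_peak <- y >= c(-Inf, y[-m]) & y >= c(y[-1], Inf) & y > 0
  peaks <- order(y, decreasing = TRUE)
  peaks <- peaks[is_peak[peaks]]
  # enforce a minimal spacing of 3 bins between chosen peaks
  chosen <- integer(0)
  for (p in peaks) {
    if (all(abs(p - chosen) > 3)) chosen <- c(chosen, p)
    if (length(chosen) == n_components) break
  }
  mu <- hist$mids[chosen]
  if (length(mu) < n_components) {
    extra <- stats::quantile(rep(hist$mids, hist$counts),
                             probs = seq(0.1, 0.9,
                                         length.out = n_components))
    mu <- c(mu, extra[!extra %in% mu])[seq_len(n_components)]
  }
  mu <- sort(mu)
  sigma <- rep(max(hist$bin_width * 2,
                   diff(range(hist$mids)) / (12 * n_components)),
               n_components)
  dens <- hist$counts / (hist$n_samples * hist$bin_width)
  a <- vapply(mu, function(m0) {
    h <- dens[which.min(abs(hist$mids - m0))]
    max(h, 1e-6) * sigma[1] * sqrt(2 * pi)
  }, numeric(1))
  list(A = a, mu = mu, sigma = sigma, C = 0)
}

#' Fit a sum of Gaussians to an amplitude histogram
#'
#' Least-squares fit of
#' \deqn{f(x) = \sum_{i=1}^{n} \frac{A_i}{\sigma_i \sqrt{2\pi}}
#'   e^{-(x-\mu_i)^2 / 2\sigma_i^2} + C}
#' to the density-normalized histogram (counts / (n_samples * bin_width))
#' against the bin centers, by Levenberg-Marquardt. `A_i` is the area
#' weight, `mu_i` the level mean (pA), `sigma_i` the level spread (pA) and
#' `C` a constant offset. Components are returned ordered by increasing
#' mean. Spreads are bounded below at half the bin width, area weights at
#' zero. Non-convergence is reported in the `converged` flag together with
#' the optimizer diagnostics, never silently.
#'
#' @param hist an [amplitude_histogram()].
#' @param n_components number of Gaussian components (>= 1).
#' @param init optional list with starting values `A`, `mu`, `sigma`, `C`.
#' @return An object of class `gaussian_mixture_fit`: `components` (data
#'   frame with columns `A`, `mu`, `sigma`), `C`, `n`, `converged`,
#'   `message`, `rss`, `r_squared`, plus the data used in the fit.
#' @examples
#' m <- two_state_model(60, 60, conductance_pS = 96.5)
#' tr <- simulate_patch(m, voltage = 100, duration = 5, seed = 7)
#' fit <- fit_gaussian_mixture(amplitude_histogram(tr), 2)
#' unitary_amplitude(fit)
#' @export
fit_gaussian_mixture <- function(hist, n_components, init = NULL) {
  stopifnot(inherits(hist, "amp_hist"))
  n_components <- as.integer(n_components)
  if (n_components < 1) stop("'n_components' must be >= 1")
  n_free <- 3L * n_components + 1L
  if (sum(hist$counts > 0) <= n_free)
    stop("too few occupied bins (", sum(hist$counts > 0),
         ") for ", n_free, " free parameters")
  x <- hist$mids
  y <- hist$counts / (hist$n_samples * hist$bin_width)
  if (is.null(init)) init <- mixture_init(hist, n_components)

  nc <- n_components
  unpack <- function(par) list(A = par[seq_len(nc)],
                               mu = par[nc + seq_len(nc)],
                               sigma = par[2 * nc + seq_len(nc)],
                               C = par[3 * nc + 1])
  model_y <- function(par) {
    p <- unpack(par)
    rowSums(vapply(seq_len(nc), function(i) {
      p$A[i] * stats::dnorm(x, p$mu[i], p$sigma[i])
    }, numeric(length(x)))) + p$C
  }
  par0 <- c(init$A, init$mu, init$sigma, init$C)
  lower <- c(rep(0, nc), rep(-Inf, nc), rep(hist$bin_width / 2, nc), -Inf)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower,
    fn = function(par) y - model_y(par),
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                         ptol = 1e-12))
  p <- unpack(fit$par)
  ord <- order(p$mu)
  comps <- data.frame(A = p$A[ord], mu = p$mu[ord], sigma = abs(p$sigma[ord]))
  rss <- sum(fit$fvec^2)
  tss <- sum((y - mean(y))^2)
  structure(list(components = comps, C = p$C, n = nc,
                 converged = fit$info %in% 1:3,
                 message = fit$message,
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 bin_width = hist$bin_width,
                 voltage = hist$voltage,
                 x = x, y = y),
            class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d component(s), %s (R^2 = %.4f)\n",
              x$n, if (x$converged) "converged" else
                paste("NOT converged:", x$message),
              x$r_squared))
  print(format(x$components, digits = 4))
  cat(sprintf("  offset C = %.4g\n", x$C))
  invisible(x)
}

#' Unitary current amplitude from a mixture fit
#'
#' The single-channel current is the difference between the means of the
#' first open level and the baseline (closed) level: the baseline is the
#' component nearest 0 pA and the unitary amplitude is `mu2 - mu1` taken
#' towards the adjacent component, so the result carries the sign of the
#' current at that voltage.
#'
#' @param fit a [fit_gaussian_mixture()] result with >= 2 components.
#' @param baseline index of the baseline component; default the component
#'   with mean closest to 0 pA.
#' @return Unitary amplitude in pA. A single-component fit yields
#'   `NA` with attribute `reason = "no opening detected"` (a channel that
#'   never opened, not a zero-amplitude one).
#' @export
unitary_amplitude <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  if (fit$n < 2)
    return(structure(NA_real_, reason = "no opening detected"))
  mu <- fit$components$mu
  b <- if (is.null(baseline)) which.min(abs(mu)) else as.integer(baseline)
  others <- setdiff(seq_along(mu), b)
  nb <- others[which.min(abs(mu[others] - mu[b]))]
  mu[nb] - mu[b]
}

# Map each mixture component to an integer conductance level: level 0 at
# the baseline, increasing away from it in the direction of the open-level
# means.
component_levels <- function(fit, baseline = NULL) {
  mu <- fit$components$mu
  b <- if (is.null(baseline)) which.min(abs(mu)) else as.integer(baseline)
  dir <- if (length(mu) > 1) sign(mean(mu[-b]) - mu[b]) else 1
  if (dir == 0) dir <- 1
  rank(dir * (mu - mu[b])) - 1L
}

#' Idealize a trace by half-amplitude threshold crossing
#'
#' Assigns every sample the conductance level whose fitted mean is nearest
#' (equivalently, thresholds at the midpoints between adjacent level
#' means — the half-amplitude criterion), then merges events shorter than
#' the dead time into their neighbours and run-length encodes the result.
#' The default dead time is the standard Gaussian-filter resolution limit
#' 0.179 / filter_cutoff. Idealized dwell durations sum exactly to the
#' trace duration.
#'
#' @param trace a [pq_trace()].
#' @param fit a [fit_gaussian_mixture()] supplying the level means.
#' @param dead_time shortest resolvable event, s; events shorter than this
#'   are absorbed into the adjacent (longer) dwell. Default
#'   `0.179 / filter_cutoff` when the trace declares a cutoff, else 0.
#' @param baseline passed to [component_levels()]; default: component with
#'   mean nearest 0 pA is the closed level.
#' @return An [ideal_trace()]; if adjacent level means are separated by
#'   less than 3 standard deviations the output carries attribute
#'   `overlap_warning = TRUE`.
#' @export
idealize_trace <- function(trace, fit, dead_time = NULL, baseline = NULL) {
  stopifnot(inherits(trace, "pq_trace"), inherits(fit, "gaussian_mixture_fit"))
  if (is.null(dead_time)) {
    dead_time <- if (is.finite(trace$filter_cutoff) && trace$filter_cutoff > 0)
      0.179 / trace$filter_cutoff else 0
  }
  if (dead_time < 0) stop("'dead_time' must be >= 0")
  mu <- fit$components$mu
  lv <- component_levels(fit, baseline)
  ord <- order(mu)
  mu_s <- mu[ord]; lv_s <- lv[ord]
  overlap <- length(mu_s) > 1 &&
    min(diff(mu_s)) < 3 * max(fit$components$sigma)

  # nearest level mean == half-amplitude thresholds at midpoints
  thr <- (mu_s[-1] + mu_s[-length(mu_s)]) / 2
  idx <- findInterval(trace$samples, thr) + 1L
  sample_levels <- lv_s[idx]

  r <- rle(sample_levels)
  lens <- r$lengths; levs <- r$values
  dt <- 1 / trace$sampling_rate
  min_len <- ceiling(dead_time / dt - 1e-9)
  # merge sub-dead-time events into the longer neighbour, shortest first
  while (length(lens) > 1 && min(lens) < min_len) {
    k <- which.min(lens)
    nb <- if (k == 1) 2L
          else if (k == length(lens)) k - 1L
          else if (lens[k + 1] > lens[k - 1]) k + 1L else k - 1L
    lens[nb] <- lens[nb] + lens[k]
    lens <- lens[-k]; levs <- levs[-k]
    # coalesce newly adjacent equal levels
    if (length(levs) > 1) {
      same <- c(FALSE, levs[-1] == levs[-length(levs)])
      if (any(same)) {
        grp <- cumsum(!same)
        lens <- as.numeric(tapply(lens, grp, sum))
        levs <- levs[!same]
      }
    }
  }
  out <- ideal_trace(levs, lens * dt,
                     voltage = if (length(trace$voltage) == 1) trace$voltage
                               else NA_real_)
  attr(out, "overlap_warning") <- overlap
  attr(out, "dead_time") <- dead_time
  out
}
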