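test_that("histograms conserve samples and place them in the right bins", {
  tr <- pq_trace(rep(0, 1000), 10000, voltage = 0)
  h <- amplitude_histogram(tr, bin_width = 0.1)
  expect_equal(sum(h$counts), 1000)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$counts[h$counts > 0], 1000L)

  tr2 <- pq_trace(rep(c(0, 9.65), 500), 10000, voltage = 100)
  h2 <- amplitude_histogram(tr2, bin_width = 0.5)
  expect_equal(sum(h2$counts), 1000)
  expect_equal(sort(h2$counts[h2$counts > 0]), c(500L, 500L))

  set.seed(1)
  x <- stats::rnorm(1e5, mean = 2, sd = 0.3)
  h3 <- amplitude_histogram(pq_trace(x, 10000), bin_width = 0.02)
  m <- sum(h3$mids * h3$counts) / sum(h3$counts)
  expect_lt(abs(m - 2), 3 * 0.3 / sqrt(1e5) + 0.02 / 2)
  expect_error(amplitude_histogram(pq_trace(1:5, 10), bin_width = -1), "> 0")
})

test_that("mixture fitting recovers exact two-component parameters", {
  # histogram whose density IS the target mixture (no sampling noise)
  mids <- seq(-1.5, 11.5, by = 0.05)
  f <- 1000 * stats::dnorm(mids, 0, 0.3) + 300 * stats::dnorm(mids, 9.65, 0.3)
  h <- structure(list(bin_edges = c(mids - 0.025, max(mids) + 0.025),
                      counts = f * 0.05, mids = mids, bin_width = 0.05,
                      voltage = 100, n_samples = 1),
                 class = "amp_hist")
  fit <- fit_gaussian_mixture(h, 2)
  expect_true(fit$converged)
  expect_equal(fit$components$A, c(1000, 300), tolerance = 0.01)
  expect_equal(fit$components$mu, c(0, 9.65), tolerance = 0.01)
  expect_equal(fit$components$sigma, c(0.3, 0.3), tolerance = 0.01)
  expect_lt(abs(fit$C), 1)
})

test_that("a single component on symmetric data sits at the sample mean", {
  set.seed(2)
  x <- stats::rnorm(2e4, mean = 1.7, sd = 0.4)
  fit <- fit_gaussian_mixture(amplitude_histogram(pq_trace(x, 1e4)), 1)
  expect_true(fit$converged)
  expect_equal(fit$components$mu, mean(x), tolerance = 0.01)
})

test_that("peak separation of a 57.2 pS channel at +100 mV is recovered within 1%", {
  m <- two_state_model(50, 50, conductance_pS = 57.2, opening_v_slope = 100)
  tr <- simulate_patch(m, 100, 10, seed = 21)
  fit <- fit_gaussian_mixture(amplitude_histogram(tr), 2)
  expect_true(fit$converged)
  expect_equal(diff(fit$components$mu), 5.72, tolerance = 0.01)
})

test_that("residual never increases when a nested component is added", {
  m <- two_state_model(60, 60, conductance_pS = 96.5)
  tr <- simulate_patch(m, 100, 5, seed = 3)
  h <- amplitude_histogram(tr)
  f1 <- fit_gaussian_mixture(h, 1)
  f2 <- fit_gaussian_mixture(h, 2)
  expect_lt(f2$rss, f1$rss + 1e-12)
  # a third component initialized as weightless keeps the n = 2 optimum
  init3 <- list(A = c(f2$components$A, 0),
                mu = c(f2$components$mu, mean(f2$components$mu)),
                sigma = c(f2$components$sigma, h$bin_width),
                C = f2$C)
  f3 <- fit_gaussian_mixture(h, 3, init = init3)
  expect_lt(f3$rss, f2$rss + 1e-12)
})

test_that("unitary amplitude is the baseline-adjacent mean difference with sign", {
  expect_equal(unitary_amplitude(fake_fit(c(0, 9.65))), 9.65)
  expect_equal(unitary_amplitude(fake_fit(c(-9, 0))), -9)
  a <- unitary_amplitude(fake_fit(0))
  expect_true(is.na(a))
  expect_equal(attr(a, "reason"), "no opening detected")
})

test_that("round-trip amplitude at +/-100 mV matches G (V - Vrev) / 1000", {
  m <- two_state_model(50, 50, conductance_pS = 96.5, opening_v_slope = 100)
  for (v in c(-100, 100)) {
    tr <- simulate_patch(m, v, 10, seed = 31 + v)
    fit <- fit_gaussian_mixture(amplitude_histogram(tr), 2)
    expect_equal(unitary_amplitude(fit), 9.65 * sign(v), tolerance = 0.02)
  }
})

test_that("amplitude estimate converges to the ohmic value as noise vanishes", {
  m <- two_state_model(50, 50, conductance_pS = 96.5)
  tr <- simulate_patch(m, 100, 5, seed = 5,
                       acq = quiet_acq(noise_sd = 0.01, seed = 5))
  fit <- fit_gaussian_mixture(amplitude_histogram(tr, bin_width = 0.002), 2)
  expect_lt(abs(unitary_amplitude(fit) - 9.65) / 9.65, 0.005)
})

test_that("half-amplitude idealization recovers a noiseless dwell sequence exactly", {
  dwell <- rep(0.010, 10)                       # 10 ms dwells = 100 samples
  lv <- rep(c(0L, 1L), 5)
  truth <- ideal_trace(lv, dwell, voltage = 100)
  m <- one_state_open(G = 96.5)
  tr <- render_current(truth, m, 100, quiet_acq())
  out <- idealize_trace(tr, fake_fit(c(0, 9.65)), dead_time = 0)
  expect_equal(out$level, truth$level)
  expect_equal(out$duration_s, truth$duration_s, tolerance = 1e-12)
  # idempotence: idealizing the re-rendered idealization returns it again
  tr2 <- render_current(out, m, 100, quiet_acq())
  out2 <- idealize_trace(tr2, fake_fit(c(0, 9.65)), dead_time = 0)
  expect_equal(out2$level, out$level)
  expect_equal(out2$duration_s, out$duration_s, tolerance = 1e-12)
})

test_that("events shorter than the dead time are merged into their neighbours", {
  fs <- 1e5
  acq <- acquisition_spec(sampling_rate = fs, filter_cutoff = 0,
                          noise_sd = 0)
  truth <- ideal_trace(c(0L, 1L, 0L, 1L, 0L),
                       c(0.010, 0.010, 5e-5, 0.010, 0.010))
  tr <- render_current(truth, one_state_open(), 100, acq)
  out <- idealize_trace(tr, fake_fit(c(0, 9.65)), dead_time = 1e-4)
  expect_equal(out$level, c(0L, 1L, 0L))
  expect_equal(out$duration_s, c(0.010, 0.02005, 0.010), tolerance = 1e-9)
  expect_equal(sum(out$duration_s), total_duration(truth), tolerance = 1e-12)
})

test_that("idealized Popen tracks the generator's true path Popen", {
  m <- two_state_model(50, 50, conductance_pS = 96.5)
  truth <- simulate_gating(m, 100, 20, seed = 77)
  tr <- render_current(truth, m, 100,
                       acquisition_spec(noise_sd = 0.3, seed = 78))
  fit <- fit_gaussian_mixture(amplitude_histogram(tr), 2)
  ideal <- idealize_trace(tr, fit)
  po_true <- sum(truth$duration_s[truth$level >= 1]) / 20
  po_est <- popen(ideal, window_s = 20)$Popen
  expect_lt(abs(po_est - po_true), 0.02)
})

test_that("baseline subtraction removes slow drift without touching openings", {
  m <- two_state_model(30, 70, conductance_pS = 96.5)   # closed-dominated
  truth <- simulate_gating(m, 100, 5, seed = 55)
  tr <- render_current(truth, m, 100,
                       acquisition_spec(noise_sd = 0.2, seed = 56))
  drift <- seq(0, 4, length.out = length(tr$samples))   # 4 pA linear drift
  tr$samples <- tr$samples + drift
  corr <- subtract_baseline(tr, n_segments = 20)
  fit <- fit_gaussian_mixture(amplitude_histogram(corr), 2)
  expect_equal(fit$components$mu[1], 0, tolerance = 0.1)
  expect_equal(unitary_amplitude(fit), 9.65, tolerance = 0.05)
})

test_that("overlapping level means are flagged", {
  tr <- pq_trace(stats::rnorm(2000, 0, 0.5), 1e4, voltage = 0)
  out <- idealize_trace(tr, fake_fit(c(0, 0.5), sigma = c(0.5, 0.5)),
                        dead_time = 0)
  expect_true(attr(out, "overlap_warning"))
})
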