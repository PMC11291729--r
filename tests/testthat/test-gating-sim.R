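test_that("a one-state always-open channel dwells at level 1 for the whole path", {
  path <- simulate_gating(one_state_open(), voltage = 50, duration = 1,
                          seed = 1)
  expect_equal(nrow(path), 1L)
  expect_equal(path$level, 1L)
  expect_equal(path$duration_s, 1)
})

test_that("dwell durations always sum exactly to the requested duration", {
  for (seed in 1:5) {
    m <- two_state_model(80, 120, opening_v_slope = 120,
                         n_channels = (seed %% 3) + 1)
    for (dur in c(0.25, 1, 3.7)) {
      path <- simulate_gating(m, voltage = 40, duration = dur, seed = seed)
      expect_equal(sum(path$duration_s), dur, tolerance = 1e-12)
      expect_equal(total_duration(path), dur)
      # consecutive dwells always change level
      if (nrow(path) > 1)
        expect_true(all(diff(path$level) != 0))
    }
  }
})

test_that("a symmetric two-state chain spends half its time open", {
  path <- simulate_gating(two_state_model(100, 100), voltage = 0,
                          duration = 100, seed = 42)
  occ <- time_at_levels(path)[["1"]] / 100
  # time-average variance ~ 2 p (1-p) tau_rel / T
  se <- sqrt(2 * 0.25 * (1 / 200) / 100)
  expect_lt(abs(occ - 0.5), 3 * se)
})

test_that("mean dwell time in each state equals 1 / exit rate", {
  alpha <- 200; beta <- 200
  path <- simulate_gating(two_state_model(beta, alpha), voltage = 0,
                          duration = 120, seed = 11)
  # drop the (stationary-initialized) first and (truncated) last dwell
  inner <- path[-c(1, nrow(path)), ]
  for (lv in 0:1) {
    d <- inner$duration_s[inner$level == lv]
    expect_gt(length(d), 1e4)
    rate <- if (lv == 0) beta else alpha
    expect_lt(abs(mean(d) - 1 / rate), 3 * stats::sd(d) / sqrt(length(d)))
  }
})

test_that("identical seeds reproduce paths and traces exactly; different seeds differ", {
  m <- two_state_model(60, 60, n_channels = 2)
  a <- simulate_gating(m, 80, 2, seed = 7)
  b <- simulate_gating(m, 80, 2, seed = 7)
  expect_identical(a$level, b$level)
  expect_identical(a$duration_s, b$duration_s)
  c <- simulate_gating(m, 80, 2, seed = 8)
  expect_false(identical(a$duration_s, c$duration_s))

  acq <- acquisition_spec(noise_sd = 0.3, seed = 5)
  t1 <- render_current(a, m, 80, acq)
  t2 <- render_current(b, m, 80, acq)
  expect_identical(t1$samples, t2$samples)
})

test_that("ohmic rendering obeys i = G (V - Vrev) / 1000", {
  m <- one_state_open(G = 96.5)
  path <- simulate_gating(m, 100, 0.1, seed = 1)
  tr <- render_current(path, m, 100, quiet_acq())
  expect_equal(unique(tr$samples), 9.65, tolerance = 1e-12)
  # zero driving force at the reversal potential
  m2 <- two_state_model(100, 100, conductance_pS = 50, reversal_mV = -20)
  p2 <- simulate_gating(m2, -20, 0.1, seed = 2)
  t2 <- render_current(p2, m2, -20, quiet_acq())
  expect_true(all(t2$samples == 0))
})

test_that("baseline noise has the requested standard deviation before filtering", {
  m <- two_state_model(1e-9, 100)  # effectively always closed
  path <- ideal_trace(0L, 10, voltage = 0)
  tr <- render_current(path, m, 0, quiet_acq(noise_sd = 0.5, seed = 9))
  expect_equal(length(tr$samples), 1e5)
  expect_lt(abs(stats::sd(tr$samples) - 0.5) / 0.5, 0.05)
})

test_that("the Bessel stage attenuates high frequencies but passes DC", {
  fs <- 50000; fc <- 5000
  t <- (0:9999) / fs
  dc <- rep(2, length(t))
  hi <- sin(2 * pi * 20000 * t)
  acq <- acquisition_spec(sampling_rate = fs, filter_cutoff = fc,
                          noise_sd = 0)
  path <- ideal_trace(1L, max(t) + 1 / fs)
  m <- one_state_open(G = 20)  # i = 20 * 100 / 1000 = 2 pA at +100 mV
  out_dc <- render_current(path, m, 100, acq)
  expect_equal(mean(out_dc$samples[1000:9000]), 2, tolerance = 1e-3)
  # filter the sinusoid through the same path by injecting it as noise
  flt <- patchquant:::bessel4_lowpass(hi, fc, fs)
  expect_lt(stats::sd(flt[1000:9000]) / stats::sd(hi), 0.05)
})

test_that("aggregate level of N identical channels is Binomial(N, p) at stationarity", {
  # time-weighted level occupancy of one long N = 3 path, batch-mean SEs
  alpha <- 70; beta <- 30; N <- 3; T <- 150
  m <- two_state_model(beta, alpha, n_channels = N)
  path <- simulate_gating(m, 0, T, seed = 123)
  p <- beta / (alpha + beta)
  tgrid <- seq(0, T - 1e-6, by = 1e-3)
  lv <- level_at(path, tgrid)
  batches <- split(lv, ceiling(seq_along(tgrid) / (length(tgrid) / 50)))
  for (k in 0:N) {
    frac <- vapply(batches, function(b) mean(b == k), numeric(1))
    se <- stats::sd(frac) / sqrt(length(frac))
    expect_lt(abs(mean(frac) - stats::dbinom(k, N, p)),
              3 * se + 1e-4)
  }
})

test_that("whole-cell step families reach density * capacitance and respect Vrev", {
  proto <- voltage_protocol("step")
  fam <- simulate_whole_cell(
    proto, density_params = list(max_density_pA_pF = 139.9, tau_ms = 2),
    capacitance = 20, acq = quiet_acq())
  expect_s3_class(fam, "step_family")
  top <- fam$traces[["+180 mV"]]
  expect_identical(max(top$samples), 139.9 * 20)
  # the 0 mV step sits exactly at the reversal potential: no current
  expect_true(all(fam$traces[["+0 mV"]]$samples == 0))
  expect_error(simulate_whole_cell(
    proto, density_params = list(max_density_pA_pF = 100, tau_ms = -1),
    capacitance = 20), "tau must be > 0")
})

test_that("noiseless whole-cell round trip recovers tau and density to 1e-6", {
  fam <- simulate_whole_cell(
    voltage_protocol("step"),
    density_params = list(max_density_pA_pF = 139.9, tau_ms = 10),
    capacitance = 20, acq = quiet_acq())
  iv <- max_current_per_step(fam)
  dens <- current_density(iv$i_max[iv$voltage == 180], fam$capacitance)
  expect_equal(dens, 139.9, tolerance = 1e-6)
  fit <- fit_activation_tau(fam$traces[["+180 mV"]])
  expect_true(fit$converged)
  expect_lt(abs(fit$tau_ms - 10) / 10, 1e-6)
})
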