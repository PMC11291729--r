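test_that("maximum step current is the signed extremum after blanking", {
  t_ms <- seq(0, 149.9, by = 0.1)
  up <- pq_trace(2798 * (1 - exp(-t_ms / 10)), 10000, voltage = 180)
  flat <- pq_trace(rep(0, length(t_ms)), 10000, voltage = 40)
  down <- pq_trace(-500 * (1 - exp(-t_ms / 10)), 10000, voltage = -100)
  fam <- step_family(list(up, flat, down), capacitance = 20,
                     protocol = voltage_protocol("step", start_mV = -100,
                                                 stop_mV = 180,
                                                 increment_mV = 140))
  iv <- max_current_per_step(fam)
  expect_equal(iv$i_max[iv$voltage == 180], max(up$samples), tolerance = 1e-12)
  expect_equal(iv$i_max[iv$voltage == 40], 0)
  expect_lt(iv$i_max[iv$voltage == -100], 0)   # inward steps keep their sign
})

test_that("maximum step current equals a brute-force scan over the window", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- pq_trace(stats::rnorm(1500, 0, 5), 10000, voltage = 100)
    fam <- step_family(list(tr), capacitance = 10,
                       protocol = voltage_protocol("step", start_mV = 100,
                                                   stop_mV = 100,
                                                   increment_mV = 20))
    got <- max_current_per_step(fam, blank_ms = 2)$i_max
    win <- tr$samples[21:1500]                 # samples after the 2 ms blank
    expect_identical(got, win[which.max(abs(win))])
  }
})

test_that("current density divides by capacitance, preserving sign", {
  expect_equal(current_density(2798, 20), 139.9)
  expect_equal(current_density(0, 13.5), 0)
  expect_equal(current_density(-500, 20), -25)
  expect_error(current_density(100, 0), "positive")
  set.seed(1)
  I <- stats::rnorm(20, 0, 100)
  expect_equal(current_density(3 * I, 17), 3 * current_density(I, 17))
})

test_that("density curve is the I-V curve scaled by 1 / Cm at every protocol voltage", {
  fam <- simulate_whole_cell(
    voltage_protocol("step"),
    density_params = list(max_density_pA_pF = 139.9, tau_ms = 5),
    capacitance = 20, acq = quiet_acq())
  iv <- max_current_per_step(fam)
  expect_equal(iv$voltage, seq(-100, 180, by = 20))
  expect_equal(current_density(iv$i_max, 20), iv$i_max / 20)
})

test_that("the monoexponential fit recovers a noiseless tau exactly", {
  fs <- 10000
  t_ms <- (0:9) / fs * 1000
  tr <- pq_trace(0 + (-2798) * exp(-t_ms / 0.06), fs, voltage = 180)
  fit <- fit_activation_tau(tr, window = c(0, 9.9 / fs * 10))
  expect_true(fit$converged)
  expect_lt(abs(fit$tau_ms - 0.06) / 0.06, 1e-6)
  expect_equal(fit$A, -2798, tolerance = 1e-6)
  expect_equal(fit$Y0, 0, tolerance = 1e-3)
})

test_that("a constant trace is flagged as amplitude-degenerate", {
  tr <- pq_trace(rep(5, 100), 10000, voltage = 180)
  fit <- fit_activation_tau(tr, window = c(0, 0.0099))
  expect_false(fit$converged)
  expect_true("amplitude-degenerate" %in% fit$flags)
  expect_true(is.na(fit$tau_ms))
})

test_that("tau is invariant to vertical offset and sign flip", {
  t_ms <- seq(0, 50, by = 0.1)
  y <- 100 * (1 - exp(-t_ms / 7))
  base <- fit_activation_tau(pq_trace(y, 10000), window = c(0, 0.05))
  off <- fit_activation_tau(pq_trace(y + 42, 10000), window = c(0, 0.05))
  neg <- fit_activation_tau(pq_trace(-y, 10000), window = c(0, 0.05))
  expect_equal(off$tau_ms, base$tau_ms, tolerance = 1e-9)
  expect_equal(neg$tau_ms, base$tau_ms, tolerance = 1e-9)
  expect_equal(neg$A, -base$A, tolerance = 1e-6)
})

test_that("tau recovery holds across decades at moderate noise", {
  for (tau in c(0.05, 0.06, 1, 10)) {
    est <- vapply(1:25, function(rep) {
      dt_ms <- tau / 20
      t_ms <- seq(0, 10 * tau, by = dt_ms)
      a <- -2798
      set.seed(1000 * tau + rep)
      y <- -a + a * exp(-t_ms / tau) + stats::rnorm(length(t_ms), 0,
                                                    abs(a) / 20)
      fs <- 1000 / dt_ms
      fit <- fit_activation_tau(pq_trace(y, fs, voltage = 180),
                                window = c(0, max(t_ms) / 1000))
      fit$tau_ms
    }, numeric(1))
    expect_lt(abs(mean(est) - tau) / tau, 0.05)
  }
})

test_that("ramp reversal potential interpolates the zero crossing", {
  n <- 5000
  v <- seq(-100, 180, length.out = n)
  ohmic <- pq_trace(0.01 * v, 10000, voltage = v)
  expect_equal(reversal_potential(ohmic), 0, tolerance = 1e-6)
  shifted <- pq_trace(0.01 * (v + 40), 10000, voltage = v)
  expect_equal(reversal_potential(shifted), -40, tolerance = 0.1)
  # no crossing in range
  out <- reversal_potential(pq_trace(0.01 * v + 10, 10000, voltage = v))
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "out of range")
  expect_error(reversal_potential(pq_trace(1:5 / 10, 10, voltage = 0)),
               "per sample")
})

test_that("reversal matches a brute-force sign-change scan on monotone curves", {
  for (seed in 1:8) {
    set.seed(seed)
    vrev <- stats::runif(1, -60, 60)
    v <- seq(-100, 180, length.out = 4000)
    i <- 0.002 * (v - vrev) + 1e-6 * (v - vrev)^3
    tr <- pq_trace(i, 10000, voltage = v)
    k <- which(sign(i[-1]) * sign(i[-length(i)]) < 0)[1]
    brute <- v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
    expect_equal(reversal_potential(tr), brute, tolerance = 0.01)
    expect_equal(reversal_potential(tr), vrev, tolerance = 0.01)
  }
})
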