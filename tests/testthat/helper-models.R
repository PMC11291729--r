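# Shared fixtures: small gating models, quiet acquisition settings, and a
# generator of random idealized traces for property checks.

quiet_acq <- function(noise_sd = 0, seed = NULL, filter_cutoff = 0) {
  acquisition_spec(sampling_rate = 10000, filter_cutoff = filter_cutoff,
                   noise_sd = noise_sd, seed = seed)
}

one_state_open <- function(G = 96.5) {
  channel_model(states = "O", levels = 1L, rates = matrix(0, 1, 1),
                conductance_pS = G, name = "always-open")
}

# random idealized trace: alternating open/closed dwells with exponential
# durations; max_level > 1 gives occasional stacked openings
random_ideal <- function(seed, n_dwells = 20, max_level = 1,
                         mean_dwell = 0.05) {
  set.seed(seed)
  lv <- integer(n_dwells)
  lv[seq(2, n_dwells, by = 2)] <- sample.int(max_level,
                                             length(seq(2, n_dwells, by = 2)),
                                             replace = TRUE)
  ideal_trace(lv, stats::rexp(n_dwells, 1 / mean_dwell), voltage = 100)
}

# hand-built mixture fit carrying only what idealization/amplitude need
fake_fit <- function(mu, sigma = rep(0.1, length(mu)),
                     A = rep(1, length(mu))) {
  structure(list(components = data.frame(A = A, mu = sort(mu),
                                         sigma = sigma),
                 C = 0, n = length(mu), converged = TRUE,
                 message = "fixture", rss = 0, r_squared = 1,
                 bin_width = 0.05, voltage = NA_real_),
            class = "gaussian_mixture_fit")
}
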