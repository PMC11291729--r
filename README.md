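# patchquant

Quantification of ion-channel activity from patch-clamp recordings, at
both the single-channel and the whole-cell scale, with a built-in
stochastic gating simulator that makes every analysis stage verifiable by
parameter recovery.

The package targets the standard workflow for outwardly rectifying cation
channels (e.g. polycystin-family channels recorded from primary cilia or
the plasma membrane):

* **Single channel** — all-points amplitude histograms; Gaussian-mixture
  fits f(x) = Σᵢ Aᵢ·exp(−(x−μᵢ)²/2σᵢ²)/(σᵢ√2π) + C of the closed/open
  current levels; unitary amplitude μ₂ − μ₁; slope conductance G (pS) as
  10³ × the OLS slope of i (pA) vs V (mV); half-amplitude threshold
  idealization with a dead time; open probability Popen = To/(N·T) with
  level-weighted open time To = Σ L·T_L; the literal
  NPo = To/(To + Tc); and per-series normalization to the maximum Popen.
* **Whole cell** — signed maximum current per voltage step, current
  density I/Cm (pA/pF), monoexponential activation fits
  Y(t) = Y₀ + A·e^(−t/τ), and ramp reversal potentials.
* **Simulation** — exact event-driven continuous-time Markov-chain gating
  with voltage-dependent rates, ohmic rendering
  i = G·(V − V_rev)/10³, Gaussian baseline noise, Bessel low-pass
  filtering, and a macroscopic step/ramp generator — all reproducible
  from a single seed.

## Worked example

Simulate a 96.5 pS two-state channel for 10 s at +100 mV, fit the
amplitude histogram, idealize, and measure open probability:

```r
library(patchquant)
model <- two_state_model(50, 50, conductance_pS = 96.5,
                         opening_v_slope = 100)
trace <- simulate_patch(model, voltage = 100, duration = 10, seed = 42)
fit <- fit_gaussian_mixture(amplitude_histogram(trace), 2)
fit
#> Gaussian mixture fit: 2 component(s), converged (R^2 = 1.0000)
#>        A       mu  sigma
#> 1 0.2803 0.003256 0.3238
#> 2 0.7211 9.650903 0.3216
#>   offset C = -0.0001112
unitary_amplitude(fit)
#> [1] 9.647648
popen(idealize_trace(trace, fit), window_s = 10)
#> Open probability at 100 mV (N = 1, window 0 + 10 s):
#>   Popen = 0.7203   NPo = 0.7203   To = 7.203 s   Tc = 2.797 s
```

The two mixture components sit at 0 and 9.65 pA — the closed level and
one open channel carrying G·V = 96.5 pS × 100 mV — and the channel is
open 72% of the time at this depolarized potential.

The full pipeline (simulate → histogram → mixture fit → μ₂−μ₁ →
idealize → Popen → I–V → conductance) runs from one call and writes CSV
tables plus a manifest:

```r
res <- run_pipeline(list(simulate = list(conductance_pS = 96.5)),
                    seed = 42, out_dir = "out")
res$conductance
#> Slope conductance: 96.49 pS (intercept 0.000847 pA, R^2 = 1.0000,
#>                              10 points in -100..100 mV)
```

Ten of the eleven voltages enter the fit: at 0 mV the open and closed
levels coincide, the fit is flagged as overlapping, and the point is
excluded automatically. The recovered slope matches the generator's
96.5 pS to 0.01%.

A thin command-line wrapper over the same functions is installed at
`inst/cli/patchquant` (subcommands `run`, `simulate`, `tau`, `iv`).

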