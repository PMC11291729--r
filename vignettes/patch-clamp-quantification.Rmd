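---
title: "Quantifying channel activity from patch-clamp recordings"
author: "patchquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying channel activity from patch-clamp recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchquant)
```

## Scope

patchquant quantifies voltage-clamp recordings of ion channels at two
scales. For excised-patch single-channel records (the kind obtained from
ciliary or plasma-membrane patches of cells expressing polycystin-type
cation channels) it estimates the unitary current at each voltage, the
slope conductance, and open-probability statistics. For whole-cell records
it reports maximum currents, current density, activation kinetics, and the
ramp reversal potential. Because raw recordings of this kind are rarely
deposited, the package includes a stochastic gating simulator whose ground
truth is known exactly; every analysis stage is validated by recovering
the parameters it was generated with.

## The gating model and simulator

A channel is modelled as a continuous-time Markov chain over a small set
of states, each carrying an integer conductance level (0 closed, 1 open,
larger for stacked or supra-conductance levels). Rates may depend on
voltage through per-edge exponential factors
$k(V) = k_0 e^{V/V_s}$, the standard single-barrier approximation; $V_s$
is the e-fold voltage in mV. A patch holds $N$ independent copies of the
chain. Sample paths are drawn event by event (Gillespie algorithm), so
dwell durations are exact and sum to the requested length; no time
discretization enters until rendering. The per-channel paths are summed
into the aggregate level sequence the analysis sees, and are kept
alongside it so tests can compare against per-channel truth.

Two choices deserve note:

* **Initial state.** Each channel starts from the stationary distribution
  of the generator at the command voltage. Finite observation windows are
  therefore stationary, and time-averaged open-probability estimators are
  unbiased — which is what the estimator consistency checks assume. A
  fixed initial state can be requested (`init_state`) for relaxation
  experiments; the matrix-exponential validation uses exactly that.
* **Default kinetics.** No kinetic scheme is implied by conductance and
  open-probability measurements alone, so the default fixture is the
  simplest chain that reproduces them: two states C⇌O with opening rate
  50 s⁻¹ at 0 mV, e-fold voltage 100 mV, and closing rate 50 s⁻¹. These
  give mean dwell times of tens of milliseconds — long against the
  sampling interval, so filtering does not distort amplitudes — and an
  open probability that rises with depolarization, as observed for
  outwardly rectifying cation channels. They are fixtures for validation,
  not biological claims.

### Rendering: Ohm's law, noise, filtering

Current is rendered as $i = G\,(V - V_\mathrm{rev})/10^3$ pA with $G$ in
pS and $V$ in mV, times the aggregate level, plus white Gaussian baseline
noise, then low-pass filtered. Defaults mirror common acquisition
settings: 10 kHz digitization, 5 kHz low-pass, 0.3 pA RMS noise. The
noise default keeps the mixture problem well-posed at every analysed
voltage: at ±20 mV a 96.5 pS channel produces 1.93 pA openings, about
6.4σ of separation, and ~32σ at ±100 mV — comparable to a good
excised-patch recording.

The digital filter stage is a 4-pole Bessel-type low-pass (bilinear
transform of the analog prototype with prewarped −3 dB cutoff),
chosen for its flat group delay, the property amplifier filters are
selected for. One subtlety: a 5 kHz cutoff *is* the Nyquist frequency of
a 10 kHz record. In hardware the filter acts on the analog signal before
digitization, so the digitized samples already carry its effect; a
digital filter at or above Nyquist is a no-op. The renderer therefore
applies the digital stage only when the cutoff is below 0.49 of the
sampling rate, and at the default settings treats the configured noise
as the post-filter floor. Oversampled configurations (e.g. 50 kHz
acquisition, 5 kHz cutoff) exercise the filter fully.

### Whole-cell simulation

Macroscopic step currents follow
$I(V,t) = I_{ss}(V)\,(1 - e^{-t/\tau})$ with a steady state given by a
Boltzmann activation term times the ohmic driving force,
$I_{ss}(V) \propto (V - V_\mathrm{rev}) / (1 + e^{-(V - V_{1/2})/k})$,
scaled so the current at the reference voltage (+180 mV) equals the
requested density times capacitance exactly. Defaults $V_{1/2} = 60$ mV
and $k = 30$ mV give the strong outward rectification typical of the
motivating channels; the default activation constant is 10 ms, a
realistic macroscopic value. When a test requires the plateau to be
reached exactly in double precision, it uses τ = 2 ms against the 150 ms
step, making $e^{-t/\tau}$ underflow below machine epsilon well before
the step ends. Ramp currents track $I_{ss}(V(t))$ quasi-statically —
adequate when the ramp is slow against channel kinetics, which is the
regime the protocol is designed for.

## Amplitude analysis

All-points histograms use Freedman–Diaconis bins by default
(user-overridable); counts always conserve the sample count. The
histogram density is fitted with
$$f(x) = \sum_{i=1}^{n} \frac{A_i}{\sigma_i\sqrt{2\pi}}
  e^{-(x-\mu_i)^2/2\sigma_i^2} + C$$
by Levenberg–Marquardt least squares. Component count is user-chosen, as
in interactive practice; starting values come from the tallest separated
peaks of the lightly smoothed histogram, falling back to spread
quantiles. Spreads are bounded below at half the bin width to exclude
degenerate spikes, and area weights at zero. Convergence is always
reported (`converged`, plus the optimizer message); a fit that did not
converge is never silently used. Adding a component initialized with
zero weight can only lower the residual, which is how the
residual-monotonicity property is exercised.

The unitary amplitude is $\mu_2 - \mu_1$ between the baseline component —
by default the one with mean nearest 0 pA, overridable — and its nearest
neighbour, so it carries the sign of the current. A single-component fit
yields an explicit "no opening detected" result (`NA` with a reason
attribute) rather than zero: a channel that never opened has no
amplitude, not an amplitude of 0 pA.

## Idealization

Samples are assigned to the nearest fitted level mean, which is exactly
half-amplitude threshold crossing at the midpoints between adjacent
means. Events shorter than the dead time are merged, shortest first,
into their longer neighbour (the preceding one on ties), re-coalescing
equal levels as they become adjacent; durations always sum to the trace
duration. The default dead time is the Gaussian-filter resolution limit
$0.179/f_c$ — 35.8 µs at 5 kHz, below one 10 kHz sample, so it only
matters for oversampled data. When adjacent level means are separated by
less than 3 of the largest fitted σ the output is flagged
(`overlap_warning`) rather than rejected; the pipeline excludes flagged
voltages from the conductance fit — which is also how the 0 mV sweep,
where open and closed levels coincide, removes itself.

Idealization is idempotent on noiseless data: re-rendering an idealized
trace and idealizing again returns it exactly (dwells quantized to the
sample grid).

## Open-probability statistics

For a single channel, $P_\mathrm{open} = T_o/T$ over a fixed window
(default 10 s per voltage, taken from the window start; with stationary
simulations there is no settling transient, so the default start is 0 and
both are user-settable). For $N$ channels,
$P_\mathrm{open} = T_o/(NT)$ with the level-weighted open time
$T_o = \sum_L L\,T_L$, so a dwell with two channels open counts twice.
With $N = 1$ this is identically the single-channel formula, an identity
asserted over random traces. $N$ defaults to the maximum observed
idealized level, the usual field practice, and is user-overridable; an
$N$ smaller than an observed level is an error naming both numbers.

NPo is computed literally as $T_o/(T_o + T_c)$ with level-weighted $T_o$
and $T_c$ the time at level 0. When multi-level openings occur the
denominator is not clock time and NPo is not a probability in the strict
sense; the definition is kept because it is the one in standard use, and
a strict time-fraction alternative is available behind
`per_sample = TRUE` so the discrepancy is visible rather than hidden.

Normalization divides a per-voltage Popen series by its maximum; an
all-zero series returns zeros with a flag instead of 0/0.

Slope conductance is the unweighted ordinary-least-squares slope of
unitary current (pA) against voltage (mV), times 10³ to convert pA/mV to
pS, optionally restricted to one limb of the I–V relation for channels
with distinct inward and outward conductances. Unweighted OLS is
deliberate: per-point precision varies little across voltages once the
mixture fit has converged, and weights would add a free choice with no
matching ground truth.

## Whole-cell analysis

Maximum current per step is the signed extremum (largest |I|) within the
step window after blanking the first 2 ms, a conventional guard against
capacitive transients; simulated steps have none, and the blank changes
nothing there. Current density is I/Cm. The activation fit is the
monoexponential $Y(t) = Y_0 + A e^{-t/\tau}$ with $t$ from the window
start; because a monoexponential restricted to any sub-window is still a
monoexponential with the same τ, the default blanked window does not
bias τ — unless the relaxation is essentially over before the window
opens, in which case the amplitude degenerates and the fit is flagged
(`amplitude-degenerate`, τ = NA) instead of returning a number. Fits
with τ pinned at a bound are likewise flagged. Optimizer tolerances are
set tight (ftol, ptol 10⁻¹⁵, 500 iterations) so noiseless recovery is
limited by machine precision, not the stopping rule.

Reversal potential comes from the ramp I–V smoothed with a 1 mV boxcar,
linearly interpolating the zero-current crossing; multiple crossings
return the one nearest 0 mV with a multiplicity flag, and a relation that
never crosses zero returns an explicit out-of-range result.

## Validation strategy and problem sizes

Every stage is checked against an independent oracle: matrix-exponential
occupancies for the simulator (10⁴ replicate paths, 3 binomial SE),
closed-form stationary occupancy β/(α+β) for Popen (bias below 0.01 at a
window of 100 mean dwells), binomial aggregate levels for N = 3, exact
normal-equation slopes for OLS, brute-force scans for extrema and zero
crossings, and end-to-end parameter recovery: conductances of 96.5, 89.9
and 57.2 pS are recovered within 5% from 10 s of simulated record per
voltage at default noise, and a 0.06 ms activation constant within 10⁻⁶
relative error without noise and 5% (mean of 100 replicates) at
signal-to-noise 20. These problem sizes — 10 s windows, 10⁵ samples per
sweep, hundreds of replicates — were chosen so each check resolves the
quantity it tests several times more finely than the tolerance it
asserts.

## What the simulator does not emulate

Passing these tests shows the analysis is correct for data matching the
generator's assumptions. Real recordings differ in ways the generator
deliberately omits: baseline drift and seal instability (an optional
piecewise-linear baseline correction exists but defaults off), 1/f and
flicker noise, capacitive transients and series-resistance error,
subconductance behaviour beyond what the level scheme encodes,
ligand-binding kinetics (different modulator concentrations are emulated
only as different rate sets), and rundown or modal gating
nonstationarity. Conclusions about such features need real data and,
where kinetics matter, dwell-time likelihood methods that this package
intentionally does not provide.
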