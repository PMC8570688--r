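---
title: "Modelling narrow- and broad-band gamma in mouse V1: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling narrow- and broad-band gamma in mouse V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In mouse primary visual cortex the gamma band splits into two functionally
distinct components: a narrow band (NB, [45–65] Hz) peaking near 60 Hz whose
power *decreases* as grating contrast rises from 0 to ~30%, and a broad band
(BB, [20–45] ∪ [65–95] Hz) whose power *increases* with contrast above ~30%.
This package implements, as tested and reusable code, a model-plus-analysis
chain for this phenomenon:

* a recurrent excitatory–inhibitory network of conductance-based leaky
  integrate-and-fire (LIF) neurons driven by a two-component thalamic input
  (`simulate_network`, `thalamic_rate`),
* the LFP spectral analysis used to quantify band modulations
  (`welch_psd`, `psd_modulation`, `morse_scalogram`, `derive_band_limits`,
  `band_timecourse`, `onset_latency`),
* the information-theoretic analysis of what the two bands encode
  (`mutual_information`, `range_restricted_information`, `synergy`,
  `redundancy_min_information`),
* the reduced chi-square grid searches that select the thalamic input
  parameters (`reduced_chi2`, `grid_search`,
  `piecewise_linear_input_functions`),
* phase-entrainment measures (`circular_variance_of_phase_difference`), and
* a parametric surrogate-LFP generator with known ground truth
  (`generate_surrogate_dataset`) so that the whole analysis chain is
  testable without recordings.

## The network model

The network has N = 5000 LIF neurons (80% excitatory, 20% inhibitory),
randomly and sparsely connected: every directed pair is connected
independently with probability 0.2, self-connections excluded. Membrane
potentials evolve as

    tau_m dV/dt = -(V - v_rest) + I_tot / g_leak,

with absolute-valued potentials (mV). Synaptic currents are conductance
based, `I = -g s (V - V_rev)` with `V_rev` = 0 mV (AMPA) and −80 mV (GABA).
Each presynaptic spike increments the postsynaptic gate `s` by a delayed
difference of exponentials with class-specific latency, rise and decay
constants; the kernel is scaled by `tau_m / (tau_d - tau_r)` of the
postsynaptic cell. The six (class × target) conductances and kinetics are
fixed model constants exposed by `default_synapses()`.

Integration is second-order Runge–Kutta (Heun) at dt = 0.05 ms with exact
exponential gate updates; the first 200 ms of every run are discarded. The
LFP proxy is the summed absolute GABA, recurrent-AMPA and external-AMPA
current entering the excitatory population, downsampled to 1 kHz for
analysis (the sampling rate all spectral settings assume).

### Thalamic input

Every neuron receives an independent Poisson spike train through one
external AMPA synapse, with a common time-varying rate

    nu(t) = [ S(K,t) + A(K,t) * eps_gamma(t) + theta_n * n(t) ]_+

where `eps_gamma` is unit-variance Gaussian noise band-passed by a causal
third-order Butterworth filter (center 57 Hz, bandwidth 10 Hz), `n` is
z-scored 1/f^1.5 colored noise with amplitude `theta_n` = 0.4 sp/ms, and the
rectification forbids negative rates. The per-contrast amplitudes
(`thalamic_table()`) make the two components complementary: the periodic
amplitude A falls from 40 sp/s at K = 0 to 0 at K ≥ 30, while the sustained
rate S rises from 500 sp/s at K ≤ 30 to 700 sp/s at K = 90. Two
piecewise-linear closed forms summarize this (`A(K) = 42.8 − 1.4K` on
[0, 30], `S(K) = 384.8 + 3.8K` above 30, floored at the 500 sp/s baseline
below; `piecewise_linear_input_functions()`).

For reversal-locked dynamics the amplitudes become time dependent:
`A(K,t) = A0(K) − alpha(K) f(t − t* − Dt)` and
`S(K,t) = S0(K) + beta(K) f(t − t*)`, with `f` rising linearly to 1 over
10 ms and decaying exponentially afterwards and `Dt` = 40 ms reproducing
the latency of the NB suppression. A note on units: a literal per-ms
reading of the printed decay constant would end the transient in a fraction
of a millisecond, contradicting the ~200 ms transients the time courses
show; the decay rate is therefore interpreted as 25 s⁻¹ (time constant
40 ms), which makes `f` negligible after ~200 ms as intended.

### Membrane-constant calibration

The synaptic table fixes conductances and kinetics but not the membrane
constants. With the classical values of this model family (thresholds
18 mV above rest, g_leak 25/20 nS), a single 500–1000 sp/s external train
per neuron depolarizes the membrane by only ~6 mV on average: the network
stays silent and none of the reported input–output behaviors can arise. We
therefore calibrated the unprinted constants against the model's own
stated operating points, keeping `tau_m` (excitatory) = 20 ms,
`g_leak` = 25/20 nS, `v_rest` = −70 mV and refractory periods 2/1 ms, and
setting `v_threshold` = −62 mV, `v_reset` = −67 mV for both populations and
`tau_m` (inhibitory) = 20 ms. Under these defaults, at the baseline drive
(S = 500 sp/s, A = 0):

* firing is sparse (excitatory ≪ 1 sp/s, inhibitory ~1–2 sp/s), and the
  LFP spectrum is broad;
* broad-band LFP power grows approximately linearly with S, because the
  growing inhibitory activity strengthens the cortically generated gamma;
* a periodic input component entrains an LFP narrow-band peak whose power
  grows with A and whose frequency matches the input center (frequency
  tracking across 50–65 Hz).

Two alternative calibrations were explored and rejected. Making both
populations substantially more excitable (or shrinking g_leak to a few nS)
drives the network into a sharp, self-sustained ~60 Hz inhibitory limit
cycle: the intrinsic line then ignores the input frequency (no tracking)
and dominates the narrow band regardless of A. Keeping the inhibitory
membrane fast (tau_m = 10 ms) but excitability low silences the excitatory
population completely and flattens the BB-versus-S relation. The chosen
calibration sits between these failure modes: the network behaves as a
damped gamma resonator — noisy, broad-spectrum collective dynamics that
respond to the sustained drive and readily entrain to a periodic input —
rather than as an autonomous oscillator. The excitatory population fires
only in rare fluctuation-driven events at baseline drive; inhibitory
currents dominate the LFP proxy, consistent with the usual finding that
GABA currents dominate summed-synaptic-current LFP models. All constants
remain user-overridable through `neuron_population()`.

In the frequency-tracking experiment the periodic amplitude is set to
A = 100 sp/s (the top of the explored grid) over single 10-s runs: the
identity-line property is about peak location, and the strongest periodic
input makes the entrained peak unambiguous against the network's broad
gamma. Sweeps of A and S use 2-s runs after the 200 ms discard with seeds
controlling every noise source; 6–10 repetitions per condition give stable
level means at desk scale (the original protocol used 25 repetitions of
10 s).

## Spectral analysis

PSDs are computed on z-scored traces with a Hamming-tapered Welch estimator
(500 ms subwindows, 50% overlap); 200–300 ms segments use a single whole
window. A Hamming taper without detrending is used: z-scoring already
centers the trace, and the taper choice only affects leakage, not the band
comparisons. Spectral modulation is the pointwise relative difference
against the reference contrast K = 30 on the linear power scale.

Time-frequency maps use the analytic generalized Morse wavelet with
symmetry 3 and time-bandwidth product 60 (`beta` = 20), implemented as
frequency-domain filters on a logarithmic grid (12 voices/octave, 10–120 Hz
by default). Scalograms are segmented from −100 to +400 ms around each
grating reversal, excluding the 500 ms after screen onset. Band limits
derive from the K = 90 vs K = 0 modulation profile: BB is where modulation
exceeds 20%, NB the interval between the two BB ranges.

Onset latency uses a two-stage rule per trial: the first time the band
time course stays beyond its own 25th (NB) or 75th (BB) percentile for at
least 40 ms, then a regression scan of 50-ms bins with 80% overlap in a
200 ms window around that point. "Highest slope and smallest residual" is a
double criterion; it is resolved deterministically by keeping bins whose
(sign-adjusted) slope is within 5% of the steepest and choosing the
smallest residual among them. Trials that never satisfy the 40 ms criterion
are discarded rather than forced.

## Information analysis

Responses (per-trial band power modulations) are discretized into 10
equipopulated bins by rank, which maximizes response entropy and is robust
to outliers; ties are resolved deterministically with a warning. The plugin
mutual information is corrected for limited sampling with the
Panzeri–Treves analytic bias term using Bayesian relevant-bin counts.
Range-restricted information (K < 30 or K > 30) destroys the
stimulus–response association in the complementary range by permuting
responses among those trials only, averaging the plugin value over 500
permutations; its bias is estimated by quadratic extrapolation (plugin
information on 100/50/25% trial subsets, 20 draws each, quadratic fit in
the inverse trial count) minus the *identically extrapolated* mean
shuffled-label information — extrapolating both terms makes the correction
vanish on stimulus-independent data instead of over-subtracting — and the
bias term is averaged over a 20-permutation subsample (evaluating it inside
all 500 permutations would multiply the cost ~40× without changing the
average). Significance thresholds are the 95th percentile of
corrected information over stimulus-shuffled surrogates.

Synergy uses the minimum-information redundancy: the expectation over
stimuli of the smaller stimulus-specific information
`I(K = k; R) = sum_r p(r|k) log2 p(r|k)/p(r)` of the two bands, a
definition that is non-negative by construction. The joint response is the
(NB bin, BB bin) pair over a 10 × 10 table; with ~270 trials this joint
table is strongly undersampled, so the corrected joint information (and
hence synergy) should be read as bias-sensitive — the package reports the
plugin values alongside the corrected ones for this reason.

## Model fitting

Input parameters are selected exactly as in the original procedure:
exhaustive grid search minimizing the reduced chi-square between simulated
and target modulation curves (over frequencies for the stationary model,
over time for the reversal-locked one), with the printed grids as defaults
(A, A0: 0–100 by 10 sp/s; S, S0: 500–1000 by 100 sp/s; beta: 0–400 in
eight uniform steps; alpha: 0–A0 by 10). Ties resolve to the smallest
parameter value; non-finite objective values are excluded and flagged. The
experimental target curves are not distributable, so the shipped
experiments fit simulator-generated or surrogate targets; `reduced_chi2`
accepts any externally supplied (median, SD) curves. The printed
piecewise-linear coefficients are shipped verbatim; they do not reproduce
exactly from the tabulated per-contrast optima under obvious least-squares
protocols, so `refit_input_functions()` exposes the refit rather than
silently "correcting" anything.

## Phase analysis

Band-limited phases come from the Hilbert transform after a zero-phase
(forward–backward) third-order Butterworth band-pass — zero-phase filtering
is used here, unlike the causal filter inside the input generator, because
the quantity of interest is the phase itself. Entrainment is summarized by
the circular variance of the LFP–input phase difference (0 = perfect
locking). The thalamic input has no designated BB component, so both bands
are compared against the band-filtered total input rate; this convention is
a documented choice.

## The surrogate dataset

`generate_surrogate_dataset()` emulates the trial structure and spectral
statistics of the recordings the analysis assumes: 30 s trials at 1 kHz,
reversals every 500 ms, contrasts {0, 10, 20, 30, 50, 90} with 48 trials
per level (28 at K = 90); each trial is 1/f^1.5 background plus a ~60 Hz
narrow-band component (amplitude decreasing linearly to a plateau at
K = 30, transiently suppressed after reversals at low contrast) plus a
reversal-locked broad-band burst whose amplitude grows above K = 30. The
reversal-locked envelopes follow the *measured cortical response* time
courses — NB suppression: 42 ms onset, maximal at ~107 ms; BB burst: 4 ms
onset, maximal at ~76 ms; both over by ~200 ms — which are slower than the
thalamic input transient of the network model. Two constructional points
matter for spectral fidelity: each component is built as
`filter(envelope x white noise)` rather than `envelope x filtered noise`
(multiplying band-limited noise by a fast envelope would smear its energy
outside the band), and the confining filters are zero-phase, so the bands
do not leak into each other through filter skirts. The surrogate is a
parametric additive construction, not a second neural model: passing
end-to-end tests on it shows the *analysis* recovers known structure, not
that the network model fits real mice. Real recordings differ in ways the
surrogate does not attempt to capture (non-stationary background, eye
movements, electrode artifacts, cross-band coupling).

Default amplitudes are anchored to the published magnitudes: a background
of SD 5 against NB amplitudes of 0.7 → 0.45 and BB burst amplitudes up to
3 over a 0.35 baseline, chosen so that the K = 0 vs K = 30 narrow-band and
K = 90 vs K = 30 broad-band power ratios land near the reported ~×1.9
effects while the gamma-band components stay at a few percent of the total
variance — as in cortical LFPs, whose variance is dominated by low
frequencies. This proportion matters: all PSDs are computed on z-scored
traces, so a gamma component that is a large fraction of total variance
would leak its contrast dependence into the *other* band through the
normalization. Trial-to-trial amplitude jitter is log-normal with SD 0.2
(~1.7 dB of band-power scatter): the recordings show ~4 dB of total
scatter, but that folds in across-animal and across-session variability
the surrogate does not model, so the default represents the
within-preparation share. Within the gamma range the components dominate
the local background (the NB spectral density is ~10× the background
density at 60 Hz), the per-trial NB power separates adjacent low
contrasts, and the BB effect concentrates in the early ([0–200] ms)
window, mirroring the temporal structure of the phenomenon.

## Numerical choices

* Gates are advanced by exact per-step exponential decay; spike thresholds
  are detected at step ends and spikes timed there (0.05 ms resolution).
* Initial membrane potentials are uniform on [v_rest, v_threshold); the
  200 ms discard removes the dependence on them.
* Denormal floating-point numbers are flushed to zero inside the C++ loop:
  the exponential traces otherwise linger in the subnormal range and stall
  the FPU by two orders of magnitude. Gates below ~1e−300 are physically
  zero, so results are unaffected.
* The external Poisson drive is drawn per step as a Bernoulli thinning
  (`nu dt` ≤ 0.05 in all regimes); all randomness runs through R's RNG so a
  single seed makes connectivity, noise and spikes bit-reproducible.
* Welch and Morse estimators are implemented in the package (no installed
  R package provides them in the required form) and are verified in the
  test suite against closed-form tones, chirps, Parseval's identity and
  amplitude steps.

## Problem sizes used by the shipped experiments

The packaged experiments run the full 5000-neuron network but scale the
protocol down: 2 s analyzed per run (after the 200 ms discard) with 3–10
repetitions per input level, 10 s single runs for frequency tracking, and
surrogate datasets with the full trial counts. These sizes give stable
level means for the correlation-style results while keeping a complete run
of all experiments in the tens of minutes on one CPU; users reproducing
the original protocol can raise `repetitions` and `duration` in
`experiment_config()`.

## Known limitations

* Point LIF neurons in a single layer: no multi-compartment morphology, no
  laminar structure, no plasticity, no conductance heterogeneity.
* The LFP proxy (summed absolute synaptic currents onto excitatory cells)
  has no spatial reach model; current-source-density analysis and layer
  identification require real multichannel recordings and are out of scope.
* The unprinted membrane constants are calibrated, not measured; the
  calibration section above records the target behaviors and the rejected
  alternatives, and every constant is exposed in the API.
* Experimental medians and SDs of band modulations are not shipped, so
  reduced chi-square values against real data are only available to users
  who supply their own recordings.
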