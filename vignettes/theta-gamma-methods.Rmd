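---
title: "Methods: theta-nested gamma, coupling coherence, and capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta-nested gamma, coupling coherence, and capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, the choices made where the
design was genuinely open, and what a green test does and does not
establish. No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

Three populations of leaky integrate-and-fire neurons — excitatory (EX,
n = 100), fast-inhibitory (INf, n = 50) and slow-inhibitory (INs,
n = 50) — interact through four receptor classes. Subthreshold dynamics
are linear,

$$C\,\frac{dV}{dt} = -g_L\,(V - V_{rest}) + I_{syn} + I_{ext},$$

with threshold/reset spiking and absolute refractoriness (the potential
is clamped at the reset value while refractory). Every EX cell emits
through AMPA (rise 0.5 ms, decay 2 ms) and NMDA (rise 2 ms, decay
100 ms) synapses, whose gating follows two first-order stages: an
auxiliary variable jumps by one at each presynaptic spike and decays
with the rise constant, and the gating variable obeys
$ds/dt=\alpha x (1-s) - s/\tau_d$, which saturates below one for any
spike train. NMDA currents carry the conventional magnesium block
$B(V) = 1/(1 + [\mathrm{Mg}]e^{-0.062V}/3.57)$. The two GABA-A classes
use single-stage kinetics — exponential decay plus a saturating jump
$s \to s + \alpha(1-s)$ evaluated on the value immediately before the
spike — with decay constants on the gamma timescale for INf (8 ms) and
the theta timescale for INs (100 ms). The kinetic separation of the two
inhibitory currents is the mechanism of interest: the slow current
gates the excitatory population at theta, the fast current paces gamma
volleys inside each theta window.

The LFP is defined as the arithmetic mean of the EX membrane
potentials. A rectangular current pulse applied to the EX population
only represents the sensory stimulus (published amplitude 0.8 nA,
explored range 0.5–1.5 nA). Background currents are fixed at
0.7 (1 ± 10%) nA for EX (one uniform draw per neuron, held for the
run), 0.85 nA for INf and 0.6 nA for INs.

### Conductance normalization

The published coupling table pins twelve conductances
(g_AMee = 0.03 µS, …, g_GAse = 0.06 µS). Read as raw per-synapse values
in an all-to-all network, the summed inhibitory conductances would
exceed the leak by two orders of magnitude and the inhibition-recovery
rhythms would fall at ≈ 2 Hz (INs) and ≈ 25 Hz (INf) — outside both
target bands for any membrane constants in conventional ranges. The
package therefore interprets each coupling as the **maximal total
conductance of the projection onto one target neuron** (per-synapse
weight g/n_source; under Bernoulli wiring g/(p·n_source), and each
target's realised total is additionally held at the configured value to
absorb in-degree fluctuations, in the spirit of homeostatic synaptic
scaling). With this reading both rhythms land in-band under standard
membrane constants. `conductance_scaling = "per_synapse"` preserves the
raw reading for comparison. A consequence documented under *Limitations*
is that the numerically tiny glutamatergic couplings onto interneurons
(g_AMes ≤ 0.01, g_NMes ≤ 0.0005) become dynamically inert.

### Membrane constants

The published text leaves the membrane constants unprintable, so they
are model choices constrained by the phenotype: EX cells use C = 0.5 nF,
g_L = 0.065 µS (τ_m ≈ 7.7 ms, rheobase ≈ 1.17 nA), so that the 0.7 nA
background alone is subthreshold (EX quiescent before the stimulus) and
the stimulus range straddles the escape from slow inhibition.
Inhibitory cells use C = 0.2 nF, g_L = 0.02 µS, τ_ref = 1 ms. All
reversal potentials: 0 mV glutamatergic, −75 mV GABAergic (−70 mV would
make GABA currents vanish exactly at rest, contradicting the
requirement that inhibitory classes hyperpolarize there).

### Synaptic delay and initial conditions

Two ingredients stabilise the rhythm-generating volley states and are
part of the model definition:

* a shared **4 ms transmission delay** on all gating jumps (configurable
  per receptor class). With instantaneous coupling the mutually
  inhibiting INs population settles into stable splay/cluster states —
  verified numerically: rotating clusters of ~9 cells at ≤ 2 ms delay —
  and no theta envelope exists. A 4 ms delay widens the window in which
  near-coincident cells fire together, making the full-volley state
  attracting. It also sets the gamma period of the EX–INf loop at
  ≈ 16–18 ms (55–60 Hz).
* **initial conditions**: EX and INf start at random subthreshold
  potentials; INs start together at rest. The synchronous INs state is
  stable once reached but is not reached from scattered phases, in
  either dense or sparse wiring; the quiescent common start selects the
  oscillatory branch deterministically.

Both are exposed in `network_config()`; the methods above were chosen
once from the synchronisation analysis, not per experiment.

## Analysis stack

* **Morlet spectrogram** (`morlet_transform`): frequency-domain
  convolution with Morlet wavelets, centre parameter ω₀ = 6 cycles.
  Coefficients are normalised so a tone of amplitude A has ridge
  modulus A — band amplitudes are read in millivolts. "Amplitude" is
  the modulus; squared modulus ("power") is available via
  `band_mean_amplitude(..., power = TRUE)`; all comparisons in the
  package are made on amplitudes.
* **Band amplitudes**: frequency-mean over 4–8 Hz (theta) or 30–70 Hz
  (gamma) per time point, then time-mean over the analysis window.
* **Theta phase and phase variation**: per-neuron zero-phase band-pass
  4–8 Hz plus Hilbert transform; dispersion across neurons is the
  circular variance 1 − R at each time, time-averaged. The circular
  statistic satisfies the contract "zero iff all neurons share one
  phase"; an unwrapped-variance alternative is provided
  (`statistic = "linear"`) for sensitivity checks.
* **Coupling coherence** (`cfc_matrix`): the phase signal of each
  2–20 Hz band (1 Hz steps, 2 Hz passband) is binned into N = 18
  intervals; the mean amplitude envelope of each 30–70 Hz band (2 Hz
  steps, 4 Hz passband) per bin is normalised to a distribution P, and
  the coherence is D_KL(P‖U)/log N (natural logs; 0·log 0 := 0). The
  scalar is the mean over all bank pairs; `theta_rows_only = TRUE`
  restricts to 4–8 Hz phase rows.
* **Filters**: zero-phase frequency-domain band-passes with
  raised-cosine skirts. The transition width is a real degree of
  freedom: a gamma carrier amplitude-modulated at theta frequency f
  carries the modulation in sidebands ±f Hz from the carrier, *outside*
  a 4 Hz passband. Any sharp filter (including a forward-backward
  4th-order Butterworth, which attenuates those sidebands by > 70 dB)
  erases the modulation and the KL index becomes structurally zero —
  numerically verified on the synthetic fixture. The amplitude bank
  therefore uses 8 Hz skirts per side (passband unchanged), which pass
  theta-rate sidebands at reduced gain; the KL index is invariant to
  amplitude scale, so skirt attenuation does not bias it. The phase
  bank keeps 1 Hz skirts.
* **Nested-subcycle counting** (`count_nested_spikes`): theta cycles
  are delimited by 2π→0 wraps of the Hilbert phase of the theta-band
  LFP; the pooled EX spike train is binned at 1 ms, smoothed with a
  3 ms boxcar, and gamma events are local maxima above 20% of the
  window's peak rate with ≥ 10 ms separation (one period at the 100 Hz
  gamma upper bound). Counting depends only on LFP phase and spikes, so
  it is invariant to LFP scaling.
* **Windows**: filters and transforms are applied to the full
  recording; analysis windows only select samples. A 500 ms warm-up is
  discarded by default. Phase bands whose 18 bins cannot all be filled
  inside a window raise an error by default (`on_empty = "na"` drops
  the row instead, used by the sweep machinery where the 2–3 Hz rows
  are unresolvable in 1.5 s windows).

## Experiments and the synthetic fixture

`run_sweep` runs one simulation per (grid value × seed) and collects
theta/gamma amplitudes, both coupling scalars, phase variation, firing
rates. Direction claims are always evaluated on seed-averaged curves.
The learning scenarios apply the published four-stage conductance
sequences (IT-like: g_NMee, g_NMes, g_GAse rising together;
hippocampus-like: g_GAfe, g_GAff, g_GAsf rising together with a ±15%
theta-equivalence margin — the margin is this package's
operationalisation of "no corresponding change"). `capacity_sweep`
sweeps the stimulus over 0.5–1.5 nA, locates the theta-amplitude argmax
on the seed-averaged (lightly smoothed) curve, and reports the nested
count, gamma peak frequency and phase variation there. The low/high
gamma regimes for the capacity experiment are selected by
`capacity_variant()`, which moves the gamma spectral peak using only
the knobs shown to control gamma content (g_GAfe, g_GAse, interneuron
background), each within its printed range.

The **synthetic fixture** (`generate_coupled_signal`) is
$s(t)=A_\theta\sin(2\pi f_\theta t) + A_\gamma(1+m\sin(2\pi f_\theta
t))\sin(2\pi f_\gamma t)+\epsilon$, a clean theta carrier whose phase
modulates a gamma envelope with controllable depth m and Gaussian
noise. It emulates exactly one feature of real LFPs — phase-to-amplitude
dependence — and none of the others (no 1/f background, no bursts, no
non-stationarity, no harmonics). A green fixture test therefore
establishes that the estimator detects and ranks modulation depth, not
that it is unbiased on realistic signals.

The **downstream readout** is a single LIF cell driven by the pooled EX
spike train through one shared AMPA gating (weight 0.05 µS, membrane
τ ≈ 20 ms, refractory 12 ms ≈ one gamma period, no background). The
published wiring gives no weights; this readout is designed to report
distinct gamma volleys — it integrates across one volley, fires at most
once per volley, and is silent without input.

## Numerical choices

Gating decays use exact exponential factors; the two-stage gating uses
an exponential-Euler step with the drive frozen over the step (this
preserves the [0, 1) bound for any input); membranes use forward Euler
at dt = 0.05 ms, stable at the stiffest (AMPA, 0.5 ms) timescale.
Spikes are detected by threshold crossing at step end and timestamped
at the end of the step; delayed gating jumps are delivered through ring
buffers at step granularity. Traces are recorded at 1 ms (1 kHz), ample
for the 70 Hz analysis ceiling. All randomness (connectivity,
background heterogeneity, initial EX/INf states, fixture noise) flows
through named substreams of the single run seed, so adding a consumer
never perturbs the others and reruns are bit-identical.

## Limitations

* **Inert weak couplings.** Under projection-total scaling the printed
  EX→INs couplings (AMPA ≤ 0.01, NMDA ≤ 0.0005 µS) and EX→INf NMDA
  contribute ≲ 1% of an interneuron's drive margin; sweeps of g_NMes
  and g_NMef are flat, and the published directions for them are not
  reproduced (the corresponding acceptance assertions are left
  failing). The published effects of those couplings are only
  consistent with an unscaled per-synapse reading, which is itself
  inconsistent with the rhythm timescales; the package resolves the
  conflict in favour of the rhythms, which are the headline phenotype.
* **Fast-inhibition sweep reversals.** Increasing g_GAfe beyond
  ≈ 0.03 µS silences EX spiking, but the LFP gamma band stays energised
  by coherent fast IPSP ripples on the (subthreshold) EX membranes, so
  the published late-range reversal (gamma falling, theta recovering)
  does not occur here; both assertions are left failing.
* **Downstream silencing.** In the theta-only dissection the EX
  population still escapes once per theta cycle in a long burst, which
  drives the readout at a few Hz; the published fully silent readout is
  not reproduced.
* **Pre-stimulus coupling.** The INs theta clock runs (subthreshold)
  before the stimulus, so the pre-epoch LFP already carries
  theta-locked gamma ripples. The theta-row coupling scalar is
  reproducibly higher during the stimulus than before; the all-pairs
  scalar is slightly *lower* (broad weak pre-epoch coupling spreads
  over non-theta rows) — comparisons of pre versus during epochs
  should use the theta-row mode.
* **Deterministic subthreshold phases.** Without membrane noise,
  non-spiking EX cells driven by common inhibition have almost
  identical theta phases, so phase variation at subthreshold stimuli is
  near zero by construction. Phase-precision comparisons are therefore
  made across the stimulus range where the network actually spikes.
* **Test scaling.** The acceptance criteria in `tests/testthat` run at
  reduced scale (11 stimulus amplitudes × 3 seeds; 4–5 grid points × 3
  seeds per sweep) to stay inside the suite's time budget;
  `scripts/acceptance.R` runs the full 21 × 10 protocol.
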