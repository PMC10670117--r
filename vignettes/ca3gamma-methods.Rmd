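---
title: "Modeling sustained gamma-power changes in a CA3 microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sustained gamma-power changes in a CA3 microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Subanaesthetic ketamine raises gamma-band (30–100 Hz) oscillation power, and
the increase outlasts the drug by hours. Two plasticity accounts compete for
the *sustained* part of the effect. Under a disinhibition account, elevated
pyramidal activity during NMDA-receptor blockade drives activity-dependent
potentiation of **all** active glutamatergic synapses on pyramidal cells —
recurrent collaterals and external afferents alike. Under a direct-inhibition
account, AMPA-receptor upscaling is confined to the synapses whose NMDA
receptors were blocked, which in the CA3 means the **recurrent collaterals**
only. The two accounts therefore predict different spatial patterns of
AMPA-conductance scaling, and a biophysical microcircuit model can ask which
pattern actually produces a lasting gamma-power increase.

`ca3gamma` implements that experiment end to end: a theta-paced CA3 network
of Hodgkin–Huxley neurons, multiplicative AMPA scaling at recurrent
(`krec`) versus external (`kext`) pyramidal synapses, spectral analysis of a
model LFP and of the pooled spike raster, and the statistical layer
(regression of the relative gamma change on the two factors, and causal
mediation through the pyramidal firing rate).

## The network model

Three populations are simulated: 800 pyramidal cells (five compartments —
soma, a basal dendrite `Bdend`, and a three-compartment apical dendrite
`Adend1`–`Adend3`), 200 OLM interneurons and 200 basket interneurons (somata
only). All cells carry transient Na and delayed-rectifier K currents;
pyramidal compartments add an A-type K current and a hyperpolarization-
activated current (Ih); OLM cells add Ih, a high-threshold Ca current with a
first-order intracellular Ca pool, and a Ca-activated K current, which
produces burst firing followed by a Ca-dependent pause.

Synapses are conductance-based double exponentials,
$g(t) = \bar g\, N\,(e^{-t/\tau_2} - e^{-t/\tau_1})$, peak-normalized so that
the tabulated $\bar g$ *is* the peak conductance — which makes multiplicative
scaling factors act exactly on the peak. Pyramidal cells excite through AMPA
and NMDA receptors; interneurons inhibit through GABA-A receptors. Recurrent
pyramidal synapses terminate on the basal dendrite, OLM inhibition on the
second apical compartment, and all other connections on somata. Every
chemical synapse carries a 2 ms axonal/synaptic delay; the delay-sweep
experiment adds extra delay to recurrent connections only.

Wiring is random with fixed convergence: each postsynaptic cell draws its
presynaptic partners without replacement (no autapses). Background activity
arrives as independent per-cell Poisson trains — 1000 Hz AMPA and GABA-A
trains at every soma, 1000 Hz AMPA/GABA-A plus a 10 Hz NMDA train at the
distal apical dendrite of pyramidal cells (the entorhinal input) — and a
medial-septum pacemaker inhibits every interneuron with a slow
GABAergic conductance (rise 20 ms, fall 40 ms, reversal −80 mV) every
150 ms, imposing the theta rhythm.

### NMDA voltage dependence

NMDA conductances are multiplied by the standard Jahr–Stevens magnesium-block
factor $1/(1 + 0.28\,e^{-0.062 V})$ (1 mM Mg²⁺), exposed as a config toggle
(`nmda_mg`). With the block disabled the printed distal NMDA conductance
(6.5 nS peak at 10 Hz) drives the pyramidal population to tens of Hz,
baskets into depolarization block, and no gamma regime exists; the block is
therefore enabled by default. This is the package's own design choice for a
working baseline, consistent with the predecessor lineage of this microcircuit.

### Parameters that are free, and how they were fixed

The connection kinetics and peak conductances, population sizes, drive rates,
the 2 ms delay, theta period, and the analysis definitions are all taken as
printed inputs. Four groups of parameters are *not* printed anywhere and are
therefore this implementation's calibration, exposed in
`default_network_config()`:

* **channel rate equations and densities** — canonical hippocampal
  formulations (Traub-style Na/K, Boltzmann inf–tau gates for A-type K, Ih,
  high-threshold Ca; a Michaelis Ca-gated K), with densities set so that
  isolated cells rest near −67 mV, pyramidal input resistance is in the
  physiological 50–200 MΩ range, and OLM cells burst-then-pause;
* **compartment geometry** — soma 20×20 µm, basal dendrite 200×2.5 µm,
  apical compartments 150×2.5 µm, axial resistivity 100 Ω·cm;
* **convergence numbers** — P→P 15, P→B 100, P→OLM 10, B→P 50, B→B 100,
  OLM→P 10;
* **tonic somatic drives** — 0.18 nA (pyramidal), 0.05 nA (OLM), 0.30 nA
  (basket), the applied-current style of interneuron drive used throughout
  this model family. The basket current is what sustains the
  interneuron-network gamma generator against its own recurrent inhibition;
  conductance-based depolarization (leak-reversal changes) cannot do this
  because the inhibitory conductance itself scales up with basket activity.

These were calibrated *once*, against the qualitative regime the model is
known to exhibit — a dominant low-gamma LFP peak near 33 Hz nested in the
150 ms theta cycle, sparse pyramidal firing (~1–2 Hz), interneurons at
gamma-compatible rates, a non-epileptic regime extending to `krec = 37` with
an abrupt seizure-like transition beyond it — and then frozen. No parameter
is adjusted per experiment.

## Simulation engine and numerics

The integrator is a fixed-step (0.025 ms) semi-implicit scheme written in
C++: gating variables advance by exponential Euler on voltage-indexed lookup
tables of $(x_\infty, 1 - e^{-\Delta t/\tau})$ (0.1 mV grid, linear
interpolation), and each compartment's voltage is updated implicitly with
channel and synaptic conductances and axial neighbour voltages held at their
current values. Gating variables are clamped to $[0,1]$; a non-finite
voltage aborts the run with the cell and time. Halving the step moves spike
times of a driven pyramidal cell by well under a millisecond (see the test
suite), and spike detection (0 mV upward crossing, 3 ms refractory) happens
at integration resolution.

Determinism is structural: the master seed derives independent named
substreams for wiring (per population pair, so edge lists are invariant to
table order), per-cell background Poisson streams (counter-seeded, so one
cell's stream never depends on another's existence), and initial-condition
jitter (±2 mV around per-type resting values). A control/scaled pair run
with the same seed shares wiring and background event times exactly and
differs only in the scaled conductances — the pairing that defines
$\Delta\gamma$.

Voltage is recorded at 1 ms (sufficient for ≤100 Hz spectral analysis);
spike times at integration resolution. For memory economy the engine always
records the pyramidal-population mean distal and basal traces (all the LFP
needs); per-cell traces are optional.

## Analysis definitions

* **LFP**: mean over pyramidal cells of (V(`Adend3`) − V(`Bdend`)). Linear
  and common-mode rejecting by construction.
* **Spectra**: Welch's method, 1 s Hann segments, 50% overlap, one-sided
  density scaling, per-segment mean removal. The segment length is a fixed
  package default (the analysis window is 4 s, giving 7 averaged segments).
* **Gamma power**: sum of Welch power values in 30–100 Hz.
* **$\Delta\gamma$**: ratio minus one against the seed-matched control, so 0
  means no change and −1 is total loss.
* **Raster gamma**: all spike times pooled, binned at 1 ms, convolved with a
  unit-area 5 ms boxcar, then treated exactly like the LFP.
* **Mean pyramidal rate**: spikes per cell per second in the analysis window.

Each 7000 ms recording discards its first 3000 ms as equilibration.

## Experiments

`run_grid()` crosses `krec, kext ∈ {1, 1.25, 1.5, 1.75}` (the upper value
brackets the ~43% AMPA-amplitude increase measured after ketamine in
hippocampal culture), 16 seeds per condition by default (256 rows), each row
paired with its seed-matched control. `krec_sweep()` pushes recurrent
scaling far beyond the plausible range and classifies runs as epileptic when
the mean pyramidal rate exceeds 20× the paired baseline or theta structure
disappears from the pooled raster (no autocorrelation peak at the pacemaker
period); because the transition is an abrupt phase change, per-level verdicts
are closed upward. `delay_sweep()` fits, per added recurrent delay, the
least-squares slope of mean LFP gamma against `krec` over the non-epileptic
range. `voltage_probe()` reproduces the mechanism figure: an isolated
pyramidal cell, all drives silenced, recurrent conductances at 10%, one
synchronized volley onto the basal-dendrite AMPA receptors, somatic voltage
recorded from −20 to +40 ms.

The mechanism the delay sweep tests: after a pyramidal population spike, the
recurrent EPSP reaches the somata roughly half a gamma cycle later, so its
depolarization fills the gamma *trough*, partially cancelling the
oscillation as seen by the LFP — recurrent potentiation therefore *reduces*
LFP gamma while raising raster gamma and firing rates. Adding ~17 ms
(half a cycle) of recurrent delay shifts the EPSP onto the next peak and
inverts the slope; a full cycle (34 ms) restores it. In our probe, 60% of
the spike-referenced depolarization area falls in the middle half of the
33 ms cycle.

## Statistics

`fit_delta_gamma_regression()` is ordinary least squares
`delta_gamma ~ kext + krec` on the raw grid table with classical standard
errors and 95% CIs, reported through broom-style `tidy()`/`glance()`.
`mediation_analysis()` fits the linear mediator (`M ~ X`) and outcome
(`Y ~ X + M`) models on z-scored variables and reports ACME ($\hat a\hat b$),
ADE ($\hat c'$), total effect (their sum — an identity for linear models,
asserted to 10⁻¹⁰ in tests) and proportion mediated, with percentile
bootstrap intervals (1000 resamples by default) rather than the
quasi-Bayesian machinery of the R `mediation` package — asymptotically
equivalent for these linear models and a simpler contract. Mediation is run
per factor (X = `kext` or `krec`) with the other factor held at 1, with the
mean pyramidal rate as mediator and LFP gamma power as outcome.

## Synthetic fixtures

The analysis and inference layers are testable without the simulator:
`make_surrogate_lfp()` (sinusoids plus Gaussian noise, closed-form band
powers), `make_surrogate_raster()` (volleys at a known rhythm with Gaussian
jitter; zero jitter puts the pooled-raster peak exactly at the rhythm, large
jitter approaches Poisson), and `make_mediation_dataset()` (X uniform on the
grid levels, planted path coefficients). Every fixture is seed-reproducible
and every closed-form expectation is asserted in the test suite. What these
fixtures deliberately do *not* emulate is the full covariance structure of
simulator output — so green fixture tests validate the analysis code, not
the biology.

## Problem sizes and reduced profiles

Full replication of the 256-observation grid is ~512 seven-second
simulations — an overnight batch job via the `ca3sim grid` CLI, not part of
the test suite. The suite instead runs: the complete property battery on
fixtures; one full-size 7 s baseline for the spectral peak; and the
direction checks (scaling signs, krec sweep, delay sweep) on the full-size
network with 4 s recordings (1 s equilibration) and two seeds. We verified
that networks scaled below about half size lose the coherent gamma regime
even with 1/N synaptic compensation — gamma coherence needs the full basket
population — so `tiny_network_config()` (80/20/20, compensated) is reserved
for plumbing contracts (determinism, pairing, theta pacing), where it runs a
7 s protocol in seconds.

## Known limitations

* Channel kinetics are canonical rather than copied from the predecessor's
  code; quantitative rate values (e.g. interneuron rates within theta
  cycles) should be read as this parameterization's values.
* The LFP is a dendritic-voltage proxy, not a volume-conducted field; only
  differences between distal and basal compartments are meaningful.
* The magnitude of $\Delta\gamma$ at grid-range scaling factors is smaller
  here than the coefficient scale reported for the original grid; direction
  and mediation structure, not coefficient magnitude, are the reproduced
  quantities.
* Acute NMDA-receptor blockade (the drug-on state), short-term plasticity,
  gap junctions and intracellular signaling are out of scope.
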