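---
title: "Dual-mode neurochemical and electrophysiological analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode neurochemical and electrophysiological analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscvephys)
```

# The measurement problem

Carbon-fiber microinvasive probes record two signals at once from the same
brain region: fast-scan cyclic voltammetry (FSCV) reports sub-second
dopamine concentration changes, and conventional electrophysiology (EPhys)
reports local field potentials and spikes. The two modes interfere — every
FSCV scan injects a large voltage transient into the tissue that
contaminates the EPhys channel at the 10 Hz scan rate — and the FSCV
current itself rides on a background that is orders of magnitude larger
than the analyte signal and drifts on the tens-of-seconds scale. This
package implements the complete analysis chain for such recordings, plus a
synthetic session generator with exact ground truth so that every stage is
verifiable without animal data.

# FSCV chemometrics

## Signal model

The applied waveform is a triangular sweep from $-0.4$ to $1.3$ V at
400 V/s, repeated every 100 ms (an effective frame rate of 10 Hz). Each
scan yields a voltammogram of a few hundred samples; stacking scans gives
the *color plot*, the frames-by-samples current matrix that is the central
FSCV object. A measured frame is modelled as

$$ x_f = b + d_f \, \hat b + \sum_a c_{a,f}\, g_a \, t_a + \varepsilon_f $$

where $b$ is the static capacitive background, $d_f \hat b$ is slow drift
along the (unit) background shape, $t_a$ are unit-response voltammogram
templates for dopamine, pH and movement artifacts with calibration gains
$g_a$, $c_{a,f}$ are the analyte levels, and $\varepsilon_f$ is white
measurement noise.

Differential measurement removes $b$: `background_subtract()` subtracts
the frame recorded at a reference event (conventionally the value-cue
display). Because the reference frame's own noise is imprinted on every
subtracted frame, the function can average `n_ref_frames` consecutive
frames ending at the reference; the per-trial driver described below uses
a 3 s (30-frame) pre-cue window by default, which makes the residual
reference-noise contribution to the Q statistic negligible while remaining
inside the fixation period.

## Principal component regression

`fit_pcr()` performs PCA on mean-centered training voltammograms recorded
at known analyte levels, then maps retained component scores to
concentrations by least squares. Prediction is affine with an intercept
chosen so that the zero frame maps to zero concentration change; for
in-span noiseless frames recovery is exact (this is tested to machine
tolerance).

Choices that the underlying method leaves open, and how they are resolved
here:

* **Retained rank `k`.** The default rule keeps the smallest number of
  components explaining 99.5% of training variance — standard FSCV
  chemometrics practice. The rule is scale-sensitive when analyte gains
  differ by orders of magnitude, so the pipeline passes `k` explicitly
  (4: dopamine, pH, movement, drift) when the bank composition is known.
* **Residual centering.** Q is computed on residuals about the training
  mean (`center = TRUE`); raw-residual behavior is available via the flag.
* **Training bank composition.** No standard concentrations are mandated
  anywhere; the defaults in `make_standards()` (dopamine 0–200 nM, pH
  ±0.1, movement amplitudes 0.5–1, drift ±40 nA) are explicit modelling
  assumptions. The bank includes the *background drift shape* as a fourth
  pseudo-analyte: slow capacitive drift survives background subtraction,
  and keeping its direction inside the model span lets the drift loading
  absorb it instead of inflating Q. The drift level range is chosen to
  cover the excursions a multi-minute session accumulates, which keeps the
  estimated drift direction accurate enough that large drifts do not leak
  into the residual.
* **Bank size.** The Jackson–Mudholkar threshold is built from *sample*
  eigenvalues of the discarded components; those only span the full
  residual space when the bank has more standards than samples per scan.
  Gating analyses therefore use banks of ≥ 140 standards against
  85-sample scans. With fewer standards than dimensions the threshold is
  badly miscalibrated — this is a structural property of the statistic,
  and the package documents rather than hides it.

## Q-residual gating and the movement veto

Frames the model cannot explain are vetoed rather than propagated.
`q_alpha()` implements the closed-form upper control limit
$Q_\alpha = \theta_1 [ c_\alpha h_0 \sqrt{2\theta_2}/\theta_1 + 1 +
\theta_2 h_0 (h_0 - 1)/\theta_1^2 ]^{1/h_0}$ on the squared residual norm,
with $\theta_i$ the power sums of the discarded eigenvalues and $c_\alpha$
the normal upper-$\alpha$ quantile ($\alpha = 0.05$ by default; the
underlying report prints no value). `apply_qc()` nulls frames with
$Q > Q_\alpha$ (reason `Q-fail`) and, independently, frames whose
subtracted voltammogram correlates above $r = 0.8$ with any movement
standard (reason `movement-correlation`). Nulled frames carry `NA` and are
*excluded*, never zeroed, by all downstream averaging. A small numerical
floor ($10^{-10}$ of the total training variance) keeps exactly
reconstructable frames from being vetoed when the training bank is
noiseless and $Q_\alpha = 0$.

## Per-trial extraction

`analyze_fscv_trials()` is the production path: each trial's epoch
(default $-2$ to $+7$ s around its value cue) is background-subtracted at
*its own* cue, predicted, and gated. Referencing each epoch locally keeps
drift excursions over the analyzed stretch to a fraction of a nA, so the
Q veto responds to genuinely unexplained signal. The global
single-reference path (`background_subtract()` then
`predict_concentrations()`) remains available and is what the operation
contracts are tested against.

## Sensitivity normalization

Electrode sensitivity (dopamine oxidation current per background current)
transfers the in vitro calibration to the implanted sensor. Recorded
currents scale with sensitivity, so `sensitivity_normalize()` divides
concentrations by $\rho = s_{\text{vivo}} / s_{\text{cal}}$ and records
$\rho$. An electrode at $0.8\times$ calibration sensitivity is thereby
corrected back to truth — the direction of the correction follows from
the physics of the current, not from the looser verbal description of
"rescaling by the ratio".

# Electrophysiology

## Artifact removal

Two complementary removers, both exact no-ops away from what they touch:

* **Spectral interpolation** (`remove_artifacts_spectral()`), for LFP
  analyses: the scan artifact is periodic, so its energy sits at 10 Hz and
  harmonics. Each harmonic bin (±1 bin) is replaced by interpolating
  magnitude linearly and phase along the shortest circular arc from two
  flanking clean bins per side, with conjugate symmetry enforced. Total
  power changes only at the interpolated bins.
* **Time-domain excision** (`remove_artifacts_time()`), for spike
  analyses: samples from 1 ms before scan onset to 2 ms after scan end are
  replaced by a least-squares cubic fit to 2 ms of clean signal on each
  side. A smoothing fit is used instead of an interpolating spline through
  individual samples deliberately: interpolants anchored on a handful of
  noisy points overshoot wildly across an 11.5 ms gap, manufacturing
  threshold crossings. Everything outside the excision windows is
  untouched sample-exactly.

## Beta-band power

`beta_power()` downsamples to 1 kHz (chained integer-factor polyphase
decimation), band-pass filters 13–28 Hz with a 4th-order zero-phase
Butterworth (applied forward–backward), computes instantaneous power, and
smooths with a unit-area 0.25 s Hanning window. Instantaneous power is the
*squared magnitude of the analytic signal* of the band-passed trace. The
alternative reading — taking the envelope of the already-squared trace —
returns $|\cos\omega t|$ for a unit tone (mean $2/\pi$), whereas the
analytic-amplitude-squared convention returns exactly $A^2$; the package
adopts the convention under which a unit 20 Hz tone reads 1.0 μV², and
offers `method = "rectify"` (square then low-pass, rescaled to the same
tone convention) as the alternative. Output power is reported raw (μV²);
baseline normalization is available in the averaging step
(`baseline = "divide"`).

## Spike detection

A deliberately simple single-threshold detector stands in for offline
spike sorting (no clustering, a documented limitation): band-pass
300–6000 Hz, robust noise scale $\sigma = \mathrm{median}(|x|)/0.6745$,
negative threshold at $-4\sigma$, trough alignment, 1 ms lockout,
fixed-window snippets. Two practical notes. First, the interpolated
stretches left by artifact excision are artificially smooth; including
them biases $\sigma$ low and floods the detector with marginal crossings,
so `exclude_times` lets the caller mask them out of the noise estimate.
Second, threshold crossings of band-limited Gaussian noise at $-4\sigma$
occur at a rate of order one per second (the Rice crossing rate
$\nu_0 e^{-u^2/2}$ with $\nu_0 \approx 3.5$ kHz for this band) — orders of
magnitude above the per-sample tail probability — so a detector at this
threshold is expected to report sparse noise events on spike-free input;
the tests assert the Monte-Carlo-derived rate.

## PSTH and ISI

`psth()` averages spike counts on an aligned grid into rates per
condition (factor levels with no events give empty rows with a warning);
`isi_histogram()` bins successive differences at 1 ms. Both are thin,
exact computations tested against Poisson theory and conservation laws.

# Alignment and averaging

`sync_streams()` fits the least-squares linear map between the two
acquisition clocks over matched occurrences of shared event codes and
reports the residual RMS; `map_time()` applies or inverts it.
`epoch_and_average()` epochs any supported series on its *native* grid
(10 Hz frames for chemistry, 1 kHz for envelopes — no cross-modal
interpolation), splits by condition, and returns mean ± standard error
with SE = SD/√n computed pointwise over non-null trials (single-trial
conditions report SE 0 and are flagged). Per-trial baselines can be
subtracted (chemistry: the value-cue frame) or divided out (power).
Trial inclusion defaults to successful forced-choice trials for the shape
task, matching how such condition averages are conventionally reported.

# Probe mechanics

For concentric layers, flexural rigidity is
$K = \sum_i E_i \pi (D_{out,i}^4 - D_{in,i}^4)/64$ — additive over layers
and quartic in diameter. With handbook moduli (fused silica 72 GPa, carbon
fiber 234 GPa, parylene-C 2.8 GPa, tungsten $3.5\times10^{11}$ N/m², all
overridable), a 90 μm silica tube computes to $2.32\times10^{-7}$ N·m²
while a parylene-insulated 7 μm carbon fiber stays below
$8\times10^{-11}$ N·m² — the three-orders-of-magnitude compliance gap that
motivates the microinvasive design. Euler buckling
($P_{cr} = \pi^2 K/(K_e L)^2$, fixed-free by default as appropriate for a
probe advanced from a guide tube) and cantilever deflection
($\delta = FL^3/3K$) quantify the insertion trade-off: longer free fiber
lengths reduce tissue trauma but lower the critical load quadratically.

# The synthetic session generator

The generator renders both streams for a simulated reward-biased eye
movement task (central cue, 2 s fixation, value cue, 4 s hold, reward;
forced-choice trials at 25% for the shape task), with ground truth stored
alongside every session and bit-identical regeneration under the same
seed.

What it emulates: the stable capacitive background with linear-plus-random
walk drift; dopamine transients after each value cue (gamma kernel, shape
2, peak latency 0.7 s, peak 100 nM for large and 50 nM for small rewards —
amplitudes in the range such cue-evoked striatal transients are reported
at); a slow pH oscillation; sporadic movement-artifact frames; 1/f LFP
background plus a broadband noise floor; beta bursts (16–24 Hz, ~3 cycles,
Poisson arrivals) with multiplicative post-cue suppression deeper for
large rewards (0.6 vs 0.25) and for contralateral cues (+0.1); an
inhomogeneous-Poisson spike train with a 2 ms refractory period and
reward-scaled post-cue rate; and the stereotyped damped-oscillation scan
artifact every 100 ms. EPhys output is quantized to the int16 grid of a
±1 mV headstage range, which also makes session files round-trip
bit-exactly.

What it does *not* emulate — and what passing tests therefore do not
establish about real data: electrode-specific voltammogram shapes and
adsorption kinetics (templates are Gaussian bumps at the correct redox
potentials, not electrochemical simulations), cross-sensor transfer error
between the training bank and the recording electrode, correlated or
non-Gaussian noise, fouling, tissue reaction, eye-movement kinematics, and
overlapping spike waveforms from multiple units. Recovery results on this
generator validate the *analysis chain*, not the biology.

# Numerical choices and problem sizes

Desk-scale analyses in the tests use the 10 kHz ADC variant of the
standard waveform (85 samples/scan) and sessions of 10–60 trials; LFP
renders run at 1 kHz (the beta analysis rate) and spike renders at the
full 30 kHz. The property suite checks, among others: Q null-rate
calibration within α ± 2% on 6000 matched-noise frames; ≥ 95% veto of
injected movement frames at 3× amplitude with ≤ α + 2% collateral nulling
(pooled over 5 sessions); unit-tone beta power within 5% and ≥ 20 dB
out-of-band rejection; spike-detection F1 ≥ 0.9 at SNR 8 after artifact
excision (the excision itself caps recall near 0.89, since 11.5% of the
recording is inside excision windows); and correct recovery of the sign of
both reward effects (dopamine up, beta ERD down, large vs small) in ≥ 95
of 100 seeded sessions at default effect sizes.

# Known limitations

* The Q threshold requires a training bank larger than the scan dimension
  to be calibrated; banks measured at a handful of concentrations cannot
  support it and should rely on the movement veto plus manual inspection.
* The spike detector is single-threshold: it reports multiunit threshold
  events, not sorted units, and its false-positive rate at $-4\sigma$ is
  the Rice rate of the band, not a per-sample tail probability.
* Spikes falling inside artifact excision windows are unrecoverable by
  construction; at a 10 Hz scan rate this removes ~11.5% of spike times.
* Sensitivity normalization assumes a linear-through-origin calibration
  curve; saturating electrodes need an explicit curve.
* Clock synchronization assumes an affine drift model between acquisition
  clocks, which is adequate for crystal-oscillator clocks over
  session-length recordings.
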