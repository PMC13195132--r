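---
title: "Methods: in vivo hippocampal electrophysiology with hippoephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vivo hippocampal electrophysiology with hippoephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoephys)
library(dplyr)
```

hippoephys implements a complete measurement pipeline for in vivo
hippocampal electrophysiology: spontaneous synaptic-current detection and
kinetics from voltage-clamp sweeps, aperiodic-corrected spectral band
powers from local field potentials (LFP), oscillation-episode detection,
event-to-phase locking with circular statistics, spike-unit
classification and burst quantification from sorted extracellular
recordings, sharp-wave-ripple (SWR) detection, and the identification of
putative PV^+^ basket cells. This vignette explains each model and its
assumptions, the tunable parameters and their defaults, the synthetic-data
generator that backs the test suite, and the numerical choices made where
the methods literature leaves the design open.

Group-level inferential statistics (mixed models, repeated-measures ANOVA)
are deliberately out of scope: the pipeline emits tidy per-cell,
per-unit and per-event tables that any statistics package can consume.

## Conventions

All times are seconds from recording start; intervals are half-open
`[start, end)`; channels are mapped to shanks via the signal metadata.
Instantaneous phase uses the analytic-signal (cosine) convention — phase 0
at the oscillation peak, ±π at the trough. The basket-cell analysis uses
trough-referenced degrees (trough = 0°/360°), obtained as
`(phase + pi) mod 2pi`. Raw signals travel as flat little-endian int16
binary with a JSON sidecar; all event tables are CSV.

## Signal conditioning

Mains interference (50, 100, 150, 250 Hz) is removed with second-order
Butterworth band-stop filters. Published pipelines usually state the
order but not the stop-band width; we use a fixed 2 Hz width,
narrow enough to spare the delta–gamma bands, and pad the
forward–backward pass with odd-symmetric extensions spanning the notch
transient (3/width seconds) so epoch boundaries are not corrupted.
Signals are decimated to 2 kHz behind a linear-phase FIR low-pass (cutoff
at 80% of the target Nyquist, delay-compensated), then band-pass filtered
0.1–300 Hz with a 4th-order Butterworth.

Band-pass filters are applied as cascades of second-order sections
derived by bilinear transform of the analog Butterworth prototype. This
matters numerically: a direct high-order polynomial realization of a
1–4 Hz band at a 2 kHz rate is unstable in double precision, while the
biquad cascade is not. Zero-phase (forward–backward) application is the
default everywhere; the impulse response is symmetric about the impulse
with zero group delay.

## Welch spectra and the aperiodic model

Power spectral densities use Welch's method with a periodic Hann window
and one-sided density scaling: 10 s windows, 0.1 Hz step, 50% overlap for
LFP; 2 s windows, 0.5 Hz step, 90% overlap for synaptic-current sweeps
(which are first drift-corrected by subtracting the sweep mean).
Band-integrated PSD matches signal variance to within a few percent
(Parseval), which the test suite asserts.

Line-contaminated bins are repaired by replacing bins within ±1 Hz of
each mains frequency with the mean of the nearest clean flanking bins.

The spectrum is then parameterized into an aperiodic component and
Gaussian peaks, in the style of spectral parameterization
("FOOOF"-type) models, in fixed (knee-free) mode:

$$\log_{10} P(f) = \text{offset} - \text{exponent} \cdot \log_{10} f$$

fitted over 1–100 Hz. The fit is made robust to oscillatory peaks by
refitting on the bins whose positive residual from an initial
least-squares fit is at or below its 2.5th percentile. Up to 6 Gaussian
peaks are then detected iteratively on the flattened spectrum wherever it
exceeds 2 SD of the flattened residual, with full-width bounds of
0.5–12 Hz and an absolute minimum height of 0.1 log10-power units — the
absolute floor keeps estimator noise from being fitted as periodic
structure. A peak whose fitted support crosses the fit-range edge is
discarded as an aperiodic misfit artifact rather than subtracted, because
subtracting a wide pseudo-peak hugging the 1 Hz edge shifts the recovered
offset by up to ~0.1. After peak removal the aperiodic component is
refitted. Recovery accuracy, verified per release on synthetic 1/f
signals across exponents 0.5–2 (100 seeds each, 120 s at 1 kHz): both
exponent and offset within ±0.1 in every draw.

The "peak-only" residual spectrum is `max(P - 10^model, 0)` on the linear
scale. Band powers are trapezoid areas under the residual within slow
(0.1–1 Hz), delta (1–4 Hz), theta (4–12 Hz), beta (15–25 Hz) and gamma
(30–100 Hz); normalized powers divide by the area over the normalization
range (0.1–100 Hz for LFP, 0.1–300 Hz for synaptic currents — both are
honored as per-mode presets, not reconciled). Two open points are worth
flagging. First, the slow band lies below the 1–100 Hz fit range; the
aperiodic model is extrapolated down to 0.1 Hz for the residual, since
slow-band normalized power is reported alongside aperiodic subtraction
without the range conflict being resolvable from the method description.
Second, whether normalization used raw or residual total power is not
derivable either; the residual is the default integrand and the
denominator range is a config key. Ratios (theta/delta, beta/theta,
(theta+beta)/(slow+delta)) are formed from normalized powers and flagged
`NA` when a denominator vanishes.

## Synaptic-current analytics

Detection runs on the native acquisition rate (20 kHz in the acquisition
convention) because the separation thresholds are specified in samples
(200 for EPSC, 100 for IPSC — 10/5 ms at 20 kHz); the
derivative-percentile onset analysis for phase locking runs at the 2 kHz
analysis rate.

`detect_psc()` implements a five-stage derivative detector: (1) peaks of
the first derivative exceeding mean + k·SD of the derivative trace
(k = 1.8 EPSC / 1.2 IPSC; the trace is lightly smoothed over 1 ms for
peak finding, one candidate per contiguous supra-threshold derivative
run); (2) amplitude ≥ 7 pA (EPSC) / 15 pA (IPSC), measured on the
smoothed trace from onset (where the rise began) to the end of the rising
phase; (3) event start within 1.5 / 0.3 robust SDs of baseline — baseline
and SD are the median and scaled MAD of the sweep, a choice that is
robust to event density; (4) event end (the post-peak minimum within a
40 ms horizon) within 10 / 70 pA of the start value, rejecting summating
events; (5) a minimum separation, resolved greedily by amplitude. All
five knobs were operator-tuned quantities in the original workflow
("varied based on signal noise and activity level"); the package carries
the published minima as defaults and logs every override. Rejected
candidates are returned alongside accepted events with a
`rejection_reason`, so the operating point is auditable.

Kinetics: the rise rate is the 20–80% amplitude slope; the decay tau is a
single-exponential fit between the 80% and 20% crossings of the peak.
Peak and crossing positions are taken from a 0.25 ms-smoothed copy of the
waveform while the fit uses raw samples; without this, single-sample
noise excursions bias the fit window and inflate tau by ~10% at 2 pA
noise. Events whose decay segment is too short or non-monotone get `NA`
tau and are excluded from means. Charge transfer is the trapezoid
integral of absolute deflection (nA·s over a 30 s sweep); the E/I ratio
divides excitatory by inhibitory charge per cell.

`derivative_onsets()` smooths with a 2.5 ms moving average (interpreted
as a boxcar — the plainest reading of a "2.5 ms time constant"), takes
derivative extrema of the event sign, and keeps the top p% by magnitude,
p ∈ {1, 5, 10, 15, 20, 25}.

Intrinsic properties: input resistance from the −100 pA sweep
(steady-state deflection over current), action potentials by an upward
dv/dt crossing (default 20 mV/ms, with a 20 mV minimum amplitude — the
method description gives no numbers, these are declared defaults),
per-AP threshold/peak/amplitude/max-dv/dt/half-width/width-at-threshold
with sub-sample interpolated level crossings, and the F–I curve.

## Oscillation episodes

Episodes are detected in the BOSC family: 6-cycle Morlet wavelet power on
a log-spaced grid (1–64 Hz, 0.1-octave steps), thresholded per frequency
at the 95th percentile of the χ²(2) distribution scaled to an aperiodic
background — the background is fitted on the time-averaged wavelet
spectrum itself with the same aperiodic model as above, which is what
distinguishes the fluctuation-corrected variant from classic BOSC. A
supra-threshold run must last at least 2 cycles at its frequency.

Because a Morlet wavelet smears transients, a run's duration is first
corrected by subtracting the amplitude-dependent smear width
$2\sigma_t\sqrt{2\ln(P_{max}/P_T)}$ — the time a Gaussian envelope of SD
$\sigma_t$ would stay above threshold for an instantaneous transient of
peak power $P_{max}$. Without this deconvolution a high-amplitude
1.5-cycle burst sails past the 2-cycle rule on detector bandwidth alone;
with it, sub-criterion bursts are rejected while a continuous oscillation
loses a negligible fraction of its support. Per-frequency episodes within
a band are merged by union of time supports; the epoch's mean frequency
is the duration-and-power-weighted mean of contributing rows.

On synthetic data the detector covers ≥ 95% of a continuous high-SNR 8 Hz
oscillation, covers < 10% of pure 1/f noise, and never reports a
1.5-cycle burst as an epoch of its own (scored as an ~8 Hz epoch confined
to the burst's wavelet-smeared neighborhood — noise episodes elsewhere in
the trace are bounded by the false-coverage property instead).

## Behavioral-state segmentation

Run/rest segmentation thresholds the 50 Hz treadmill speed at > 5 cm/s
(running) and < 1 cm/s (resting); 1–5 cm/s is ambiguous and excluded
from both states, and non-ambiguous segments shorter than 2 s are
discarded. Theta/non-theta segmentation combines a theta/delta (T/D)
ratio with speed: sliding 1.6 s windows at 0.8 s steps, multitaper
spectra with NW = 3 (5 DPSS tapers, computed once from the symmetric
tridiagonal formulation), theta 4–12 Hz over delta 2–4 Hz — the narrower
delta here is kept deliberately distinct from the 1–4 Hz band used in
spectral analysis, as the two appear in different procedures and are not
harmonized. The T/D ratio is linearly interpolated to sample times and
speed is aligned by sample-and-hold. Theta requires T/D > 2 and speed
> 5 cm/s; non-theta T/D < 2 and speed < 1 cm/s; everything else is
ambiguous. The window spectra are computed on an internal 250 Hz
decimation of the LFP — theta and delta lie far below that Nyquist and
the taper eigenproblem stays small.

## Phase locking

Onsets are assigned the Hilbert phase of the band-passed LFP at their
times, and only inside detected delta or theta epochs; delta and theta
are assessed independently per band. Circular statistics are the mean
resultant: $R = |n^{-1}\sum e^{i\phi}|$ with the circular mean its
argument; the Rayleigh statistic is $Z = nR^2$ with the standard finite-n
series approximation for p. Per cell, statistics are computed for each
derivative-percentile subset and the cell-level vector length averages
the per-threshold values. A threshold with fewer than 10 retained events
(a declared default; no minimum is stated in the methods literature we
follow) is reported `NA`. The cell-level "locked" call requires Rayleigh
p < 0.05 at two or more thresholds: across six nested subsets a single
"any threshold" rule would false-alarm on ~25% of unlocked cells, while
the two-threshold consistency rule keeps that at the percent level and
costs nothing on genuinely locked cells, whose most selective subsets are
always overwhelmingly significant. Cohort-level locked proportions are
reported per threshold.

## Units, bursts, ripples, basket cells

Spike width is trough-to-peak of the mean waveform; a post-trough
"peak" must be prominent (≥ 5% of spike depth above the later minimum)
or the unit is excluded as unmeasurable. The autocorrelogram first moment
is the count-weighted mean lag of the one-sided 0–50 ms ACG (1 ms bins, a
standard default; the first moment uses bin centers), with units excluded
when the ACG peak count is below 10. Classification is by strict
inequalities — pyramidal: width > 0.5 ms and first moment < 25 ms;
fast-spiking interneuron: width < 0.5 ms and first moment > 20 ms;
anything else unclassified. Rate categories use class-specific cutpoints
(pyramidal < 1 / 1–5 / ≥ 5 Hz; interneuron < 25 / 25–40 / ≥ 40 Hz) with
half-open `[low, high)` edges. Bursts are maximal runs of ≥ 3 spikes with
consecutive inter-spike intervals under 5 ms (10 and 15 ms supported for
sensitivity analysis); the burst index is bursting spikes over all
spikes, and the burst event rate divides burst count by recording time.

SWR detection: 100–250 Hz 4th-order zero-phase Butterworth, squared
Hilbert envelope, Gaussian smoothing (σ = 4 ms, truncated at ±4σ),
threshold at mean + 3 SD of the smoothed power (computed over the full
trace; a state-restricted variant is available), bounds extended to the
nearest mean crossings, duration 15–150 ms, and a ripple/control
specificity gate: within-event mean ripple power must be ≥ 4× the
identically processed 250–400 Hz control-band power, which rejects
broadband transients. One reading choice deserves its own paragraph: the
duration criterion is applied to the supra-threshold core rather than the
mean-extended bounds (which are what the reported `start_s`/`end_s` and
`duration_ms` describe). Sustained supra-threshold power is the quantity
that separates a ripple from a brief background excursion; under the
extended-bounds reading, ordinary band-noise excursions above 3 SD
inherit tens of milliseconds from the extension and pass the 15 ms
minimum, flooding the detector at realistic SNR, whereas under the core
reading the 15 ms minimum is a genuinely discriminating quantity.

Peri-SWR modulation divides each event into eight equal bins (the
central bin boundary is the event midpoint, the "SWR peak" of the binning
convention), aggregates spike counts across events, and estimates
baseline from randomly sampled non-theta, non-SWR periods matched 1:1 in
number and duration (seeded sampling). "Single-peaked" is operationalized
as: the aggregate histogram has exactly one interior local maximum and it
lies in the two central bins — the methods literature gives no formal
test, so this is a declared package decision. Theta phase preference
assigns spikes (within theta segments) the trough-referenced phase of the
FIR-filtered, Hilbert-transformed theta band, in 18° bins; preferred
phase is the circular mean, significance the Rayleigh test, with ≥ 10
in-segment spikes required. A putative PV^+^ basket cell is a unit with a
single-peaked peri-SWR pattern and preferred phase between 203° and 339°.

## The synthetic-data generator

Every detector is validated against `synthio`-generated data with exact
ground truth. What it emulates — and what it does not — bounds what
passing tests show about real recordings.

* **LFP**: the aperiodic background is white noise spectrally shaped by
  $f^{-\chi/2}$, so the target log-log slope is exact in expectation;
  oscillations are amplitude-stable sinusoids with optional Lorentzian
  broadening via slow phase diffusion (bandwidth parameter = linewidth),
  optionally confined to a time window with half-second cosine ramps;
  mains lines are sinusoids; ripples are Hann-windowed 180 Hz tone bursts
  at non-overlapping times. "Envelope SNR" is the peak tone envelope over
  the RMS of the background in the 100–250 Hz band, computed analytically
  from the aperiodic PSD model.
* **Voltage-clamp sweeps**: biexponential kernels
  (rise 0.8 ms, decay 6 ms, amplitude 20 ± 5 pA — textbook in vivo sEPSC
  kinetics, chosen once), unit-normalized, signed by polarity, at Poisson
  or von-Mises-phase-locked times (thinning against the carrier's
  analytic phase, so generator and detector share one phase convention;
  κ = ∞ degenerates to exact placement at the preferred phase), plus
  Gaussian noise and linear drift. Noise and drift magnitudes are free
  parameters of the generator, not claims about any particular dataset.
* **Spike trains**: Poisson background with an absolute refractory
  period and optional sinusoidal theta modulation by thinning; bursts
  inserted as runs of n ≥ 3 spikes at a fixed intra-burst interval, with
  background spikes guarded away from burst windows so ground-truth
  burst counts are exact.
* **Speed**: block-structured means with Gaussian jitter at 50 Hz,
  clipped at zero.
* **Current clamp**: single-time-constant membrane responses obeying
  Ohm's law, with stereotyped Gaussian action potentials whose width
  parameter is calibrated analytically so that the analysis convention
  (threshold at the dv/dt crossing, width at half height above threshold)
  recovers the nominal half-width.

Fixed seeds give bit-identical output and the caller's RNG state is
restored. What the generator does not emulate: non-stationary background,
electrode drift and artifacts, spike-sorting errors, correlated
multichannel structure beyond independent channels, or conductance-based
neuron dynamics. Detector performance on real recordings therefore still
depends on the operator-facing thresholds that the original workflow
explicitly left tunable.

## Problem sizes used in validation

The shipped tests and the acceptance script size their simulations as
follows, chosen to give stable statistics: aperiodic recovery on 120 s
signals at 1 kHz, 100 seeds per exponent; PSC detection on five 30 s
sweeps at 20 kHz (about 750 ground-truth events pooled); SWR detection on
five 60 s traces with 20 injected ripples each at envelope SNR 4;
episode detection on 10 s traces; phase-locking separation on paired
locked/unlocked sweeps (κ = 4 versus unlocked, 50–100 pairs); Rayleigh
calibration on 1000 uniform simulations; and a 259-unit synthetic
fast-spiking cohort with 40 designed basket cells for the classifier
proportion.

## Known limitations

* The aperiodic model is knee-free; spectra with a genuine knee will bias
  the exponent.
* Episode detection inherits the wavelet's time-frequency tradeoff; the
  smear correction is a first-order deconvolution, not an inverse.
* The SWR threshold statistics include event periods by default
  (mean + 3 SD over the full trace), so extremely event-dense recordings
  raise their own threshold; the exclude-and-iterate variant is available
  behind a config flag.
* Operator-tuned thresholds are reproduced as their published minima;
  matching a specific lab's operating point requires per-run overrides,
  which the manifest records.
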