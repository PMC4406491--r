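---
title: "Models and methods behind isofatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isofatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofatigue)
```

`isofatigue` simulates and analyses repeated-maximal-contraction fatigue
experiments: 20 sets of 8 isokinetic knee extensions at 240°·s⁻¹ (each
contraction covering 90° of motion, hence lasting 375 ms), torque and
angular velocity sampled at 100 Hz, surface EMG of the knee extensors at
2048 Hz, and pre/post neuromuscular testing with femoral-nerve
stimulation. This vignette documents the models, the tunable parameters,
and the numerical choices, in the order data flow through the package.

## 1. The synthetic-data generator

Because the package is validated by parameter recovery, the generator is
the ground-truth authority: every programmed quantity must be *exactly*
what the corresponding (noise-free) extraction returns.

### Torque

A contraction's torque is a smoothstep-based unit shape scaled by the true
peak torque. Three degrees of freedom are solved per contraction so that
the extraction chain's definitions hit the programmed values exactly:

* the **rise exponent** β of `smoothstep(t/t_rise)^β` is solved so the
  ordinary-least-squares slope over the 0–75 ms samples equals the true
  RTD (at 100 Hz this is an 8-point fit);
* the **fall exponent** θ of the post-peak limb is solved so the sample
  mean over the contraction window equals the true T_mean;
* the **peak time** `t_rise` defaults to 160 ms — the reported time to
  peak torque — and lies on the sample grid, so the sampled maximum equals
  the true T_peak exactly. Only when a requested RTD/T_peak ratio is
  steeper than any rise reaching its peak at 160 ms can represent is the
  peak time shortened along the grid (with a brief plateau through the
  slope window).

Measurement noise is proportional (`torque` level, default 5% of the
instantaneous value — the error model of a torque transducer) plus a small
additive baseline floor (`torque_floor`, default 0.1% of the contraction's
peak, the magnitude of a quiet dynamometer baseline). The floor matters:
onset detectors key on it, and the recovery bias of the 8-point RTD slope
grows quickly if the baseline floor is made artificially large relative to
the early torque rise.

The angular velocity ramps linearly to the target in 57 ms, holds the
target through the contraction, and drops at the range-of-motion end; it
carries no noise (it is the servo's own control signal).

### Surface EMG

The EMG model is amplitude-modulated band-limited noise: Gaussian white
noise through a 4th-order Butterworth band-pass centered on the programmed
spectral center with proportional bandwidth (0.6 × center), normalized to
unit variance and multiplied by an amplitude envelope (a deterministic
unit-RMS sinusoid can be substituted for the noise carrier to make
envelope-recovery tests exact). The spectral center is constant except for
a programmed *early-window* drop: during the first 225 ms of the
contraction the center frequency is multiplied by a per-set factor
declining to 0.80 at the last set, emulating the early spectral
compression of fatigued EMG; later portions are untouched. The early
window is anchored at the operational (RMS-envelope) activation onset so
that it coincides with the analysis chain's 0–225 ms bins.

The envelope rises to its peak 228 ms after onset — the reported time to
peak EMG — with rise and fall exponents calibrated, like the torque shape,
so that the *deterministic chain* (expected RMS → onset detection →
0–75 ms OLS slope / window mean) returns the programmed RER and EMG_mean.
Two details make that chain exact: the expected RMS of envelope times
unit-variance carrier plus floor is `sqrt(envelope² + floor²)`, and the
floor entering the calibration is the *post-band-pass* floor — the raw
white floor loses about 36% of its amplitude to the 10–500 Hz zero-phase
filter, a factor computed from the filter's squared magnitude response.

What the generator does **not** emulate: motor-unit discharge structure,
amplitude cancellation, electrode or impedance effects, antagonist
co-activation, inter-electrode geometry. Passing recovery tests therefore
demonstrate that the *signal-processing chain* is correct and unbiased
under a realistic stochastic surface-EMG amplitude/spectrum model — not
that it would be unbiased against every physiological signal.

### Evoked responses, IMVC, metabolic data

Evoked twitches are bi-exponential, `K(e^(−t/τ_decay) − e^(−t/τ_rise))`,
normalized so the sampled maximum equals the programmed amplitude. The
rise constant is solved so the maximal central-difference derivative of
the sampled waveform equals the programmed evoked RTD; at a 100-Hz torque
rate this model can represent derivative maxima between roughly 23 and 45
times the peak, and subject draws are kept inside that range. Three
stimulations per phase are generated and the analysis averages the three —
the testing procedure's own convention — which also reduces the
Monte-Carlo error of the evoked metrics. IMVC trials hold a plateau at the
true IMVC with a superimposed twitch of amplitude
`(1 − VA/100) × eT_peak` added at the stimulation instant. VO₂ follows
`A − (A − y0)·e^(−t/τ)` sampled as 30-s means; lactate is a pre/post pair.

### Subjects, declines, seeding

Per-subject baselines are drawn log-normally around the configured means
(positivity), with physiologically coupled ratios (RTD/T_peak,
T_mean/T_peak, RER/EMG_peak, …) drawn and clamped so that every set of
every subject stays inside the shape models' representable ranges. Decline
schedules are linear in set index from 1 at set 1 to the configured end
fraction at the last set; pre/post neuromuscular changes are applied as
exact multiplicative factors. The programmed changes are homogeneous
across subjects — between-subject spread enters through baselines, not
through the true declines — so a recovery experiment estimates a single
known truth and its standard error reflects measurement noise only.
Within-set decline is exposed as a parameter and defaults to flat, since
block reporting averages over sets anyway.

All randomness derives from one master seed; each (subject, stream) pair
gets a collision-free derived seed, so regenerating only a subset (for
example EMG for only the first and last sets) leaves every other stream
bit-identical.

## 2. Extraction chain

**Onset detection** is a baseline-referenced two-stage search: the first
run of at least `min_hold` seconds entirely above
`baseline mean + 3 SD` *that contains the global signal maximum* (so
isolated baseline bumps cannot win), followed by a walk-back to the last
sample within one baseline SD of the baseline mean. The walk-back is exact
on noise-free traces; it is bounded (`max_lookback`, 30 ms for RMS
envelopes whose centered 50-ms window smears at most half a window before
the true onset), and if no baseline-level sample exists inside the bound
the most baseline-like sample is taken. For the exercise protocol the
*contraction* onset is taken from the angular-velocity channel by default:
the servo-controlled lever's movement onset is sharp for every subject,
whereas a torque-threshold onset is ill-defined for contractions whose
early torque rise is flatter than the noise floor (at 100 Hz a one-sample
onset error changes the 8-point RTD slope by 15–30%). Torque-channel
detection remains available (`onset_channel = "torque"`) and the EMG
activation onset is always detected on the RMS envelope itself.

**RTD and RER** are OLS slopes over `onset ≤ t ≤ onset + 75 ms`; at
100 Hz the 75-ms bound never lands on a sample, so the window simply
contains 8 samples with no interpolation. Both definitions agree with the
endpoint slope on linear data. **T_mean/T_peak** are computed over
`[onset, isokinetic end]`, the isokinetic end being the last sample whose
velocity is within 5% of the target; the EMG window end is tied to the
same point. **Evoked metrics** use the baseline-corrected response: peak,
and maximal central-difference derivative. **VA** clips to [0, 100] with a
warning, since noise can drive the superimposed twitch negative. The
superimposed twitch is measured as the post-stimulus maximum minus the
torque level at the stimulation instant; with plateau noise this estimator
is biased upward on both sides of the exercise, so VA levels are biased
low but the pre-to-post VA change is preserved — a known limitation of
twitch interpolation on noisy plateaus.

## 3. Wavelet time–frequency analysis

The bank's center frequencies follow the second-degree polynomial law
`F_aj = (1/scale)(j + q)^r` with `scale = 0.3`, `q = 1.45`, `r = 1.959`,
11 wavelets spanning 6.90–395.4 Hz. The transform is a frequency-domain
Morlet CWT (non-dimensional carrier ω₀ = 6, configurable): the signal is
zero-padded to the next power of two, multiplied in the Fourier domain by
unit-energy daughter wavelets whose scales are chosen so each wavelet's
Fourier-equivalent frequency equals its bank center, and transformed back.
Intensity is the squared coefficient modulus — instantaneous power, not a
Gauss-smoothed intensity; smoothing is deliberately left out because the
instantaneous mean frequency is itself an intensity ratio. `if_mean` is
the intensity-weighted centroid of the center frequencies; frames with
zero total intensity yield missing values rather than errors. Bin means
over the five 75-ms intervals exclude cone-of-influence samples (edge
artifacts would otherwise dominate bins near trace edges; the exclusion is
switchable).

Two properties of the discrete bank are worth knowing. First, a pure tone
*between* centers yields a centroid pulled toward the nearest center: an
80-Hz tone, sitting between the 62.1 and 92.4 Hz wavelets, reads as about
90 Hz. Tones at bank centers read within a few percent. The centroid is a
*relative* fatigue index, not a frequency meter, which is exactly how the
binned analysis uses it. Second, the wavelets' finite time support smears
sharp spectral transitions by roughly their envelope width, so a spectral
switch at 225 ms bleeds slightly into the neighbouring bin.

## 4. Statistics layer

Block averages normalize each subject's per-contraction values to that
subject's protocol maximum before averaging (4-set blocks; 20% intervals
of 32 contractions). Percent changes are computed per subject and then
averaged — the subject-level reporting convention — which differs from the
ratio of group means; both conventions are trivially available from the
tables. Standardized betas come from OLS on z-scored variables; forward
stepwise entry requires a partial-F p below 0.05 and guards against
collinearity (|r| > 0.9 with an included predictor). The one-way
repeated-measures ANOVA uses the condition × subject interaction as error
term with no sphericity correction by default (Greenhouse–Geisser is an
option); Tukey post hoc tests use the studentized range on that error
term. The mono-exponential VO₂ fit is initialised by a grid search over
the time constant (each candidate reduces to a linear fit) and refined by
Levenberg–Marquardt; a flat series returns its constant with the time
constant flagged unidentifiable.

## 5. Problem sizes and recovery accuracy

The packaged recovery experiments simulate 11 subjects × 160 contractions
(torque at 100 Hz; EMG generated for the first and last sets, which are
the sets entering the first-vs-last comparisons and the time–frequency
analysis; three evoked responses per test phase). Under the default noise
levels the chain recovers programmed group changes to well under one
percentage point for the torque and evoked metrics. The two intrinsically
noisy recoveries are the normalized rate of EMG rise — the 50-ms RMS of
band-limited noise carries ~30% sampling error per contraction, giving the
group-mean change a Monte-Carlo SD near 3 percentage points per simulated
experiment — and the peak-torque change, where the sampled maximum of a
noisy trace is inflated by a few percent in a shape-dependent (and hence
not perfectly cancelling) way, leaving a residual bias of a few tenths of
a point. The acceptance script therefore averages the EMG recovery over
replicate simulations; all other quantities are single-experiment values.

## 6. Known limitations

* The EMG model's spectral centroid is controllable but its discharge
  physiology is not modelled; normalized amplitude indices (nRER,
  nEMG_mean) inherit the RMS estimator's sampling noise.
* Onset-sensitive metrics at 100 Hz are fundamentally coarse; the
  velocity-anchored onset sidesteps this for the dynamometer channel but
  no equivalent exists for the EMG channel.
* The wavelet centroid is biased for content between bank centers (see
  §3); comparisons across conditions are unaffected because the bias is
  shared.
* The voluntary-activation level is biased low on noisy plateaus (see §2).
* Statistical machinery assumes complete, balanced designs; missing cells
  raise errors rather than being imputed.
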