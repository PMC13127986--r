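---
title: "Methods: spectral, coupling and place-avoidance analysis in neurocarousel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral, coupling and place-avoidance analysis in neurocarousel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocarousel)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the spirit of a methods section: what each stage
assumes, which tunable parameters matter, and where the design was
genuinely open.

## The data model

An `lfp_recording` is a uniformly sampled multichannel voltage series
(µV) with a sampling rate (the package targets 2000 Hz acquisition with
a 1–475 Hz hardware band, carried in `meta`), a start time, and
free-form provenance metadata. Analysis epochs are cut from recordings
by a `session_timeline` of labeled half-open windows `[start, end)` in
seconds — timelines are *data*, not code, so an experiment's injection
schedule (e.g. a 30-min baseline of which the last 10 min are analysed,
then post-injection windows such as injection + [1800, 2400) s) is
expressed as a small table rather than hard-wired constants. Sample
indexing is 0-based in time (`t0 + k/fs`) and every window is half-open,
which makes window sample counts exactly `round((end - start) * fs)` and
binning additive.

Trajectories are timestamped `x, y` positions in cm with a declared
reference frame, `room` (laboratory-fixed) or `arena` (rotating
disc-fixed). Coordinates are centred on the arena/box centre.

## Filtering

**Why second-order sections.** All IIR filtering is done as a cascade of
biquads. This is not cosmetic: an order-4 Butterworth band-pass for the
theta band at fs = 2000 Hz has normalized edges of 0.004–0.01, and in
single transfer-function `(b, a)` form its rounded coefficients place
poles effectively outside the unit circle — the filtered output diverges
by tens of orders of magnitude. The package therefore designs
Butterworth band-passes analytically in zero-pole-gain form (analog
prototype, band transform, bilinear transform) and factors them into
conjugate-pole second-order sections, which are numerically benign at
any bandwidth used here. Each biquad is applied with initial conditions
set to the steady state for a constant input, so a DC signal passes a
notch cascade with zero transient and edge artifacts of other inputs
stay short.

**Zero phase.** Both the notch cascade and the band-pass run forward and
backward (`filtfilt` style). A causal biquad would impose a
frequency-dependent group delay, which directly biases instantaneous
phase estimates and hence phase–amplitude coupling; the forward-backward
pass has exactly zero net phase shift at the cost of squaring the
magnitude response (attenuation in dB doubles, which only helps). The
remaining edge transient is handled by trimming a 1 s margin from each
end of any filtered epoch before phase/amplitude estimation.

**Notch parameters.** The line-noise cascade defaults to notches at
50 Hz and harmonics up to 250 Hz with quality factor Q = 30 (≈ 1.7 Hz
bandwidth at 50 Hz). The narrow bandwidth matters because 50, 100 and
150 Hz all sit inside or adjacent to the 30–55 and 55–100 Hz analysis
bands; at Q = 30 a 40 Hz probe changes by under 1 % while the 50 Hz
component drops by far more than 20 dB.

## Spectral estimation

`welch_psd()` divides the epoch into Hann-windowed segments of
`seg_len = 2` s with 50 % overlap and averages the one-sided squared
Fourier spectra, scaled by `1 / (fs * sum(w^2))`. Two seconds gives a
0.5 Hz grid — fine enough to resolve the 4 Hz theta edge — while a
10-min analysis window still contributes ~600 segments. The
normalisation is chosen so the estimate is a true density (µV²/Hz):
its integral over frequency equals the variance of a stationary input,
and a unit sine integrates to a² / 2 = 0.5. Band power is the *mean*
density over all bins with `f_lo <= f <= f_hi`, both edges inclusive
(on the 0.5 Hz grid the 30–55 Hz band averages exactly 51 bins).

Percent-of-baseline change uses the signed-difference convention
`100 * (post - baseline) / baseline`, so 0 means no change; the ratio
convention (100 = no change) is available behind a flag. The baseline
must be strictly positive, which is guaranteed for any epoch with
nonzero in-band signal or noise.

Spectrograms use a 1 s Hamming window with 75 % overlap restricted to
30–100 Hz; column times are window centres, and a T-second epoch yields
`1 + floor((T - 1)/0.25)` columns.

## Phase–amplitude coupling

The PLV pipeline per channel is:

1. band-pass the raw epoch in the phase band (theta) → Hilbert phase
   `φ_theta(t)`;
2. band-pass in the amplitude band (low or high gamma) → Hilbert
   envelope;
3. band-pass the envelope *in the phase band* → Hilbert phase
   `φ_env(t)`;
4. `PLV = |mean(exp(i(φ_theta − φ_env)))|`, preferred phase
   `= Arg(mean(...))`, computed after trimming the 1 s margins.

Step 3 deserves emphasis. The gamma envelope has a large DC component
(its mean amplitude); the phase of a signal riding on a DC offset is
confined near zero and essentially meaningless. Filtering the envelope
in the phase band removes the offset and isolates exactly the
theta-rate modulation whose phase is being compared. Without this step
the estimator collapses toward zero regardless of true coupling.

The epoch must contain at least 10 slow-band cycles after trimming;
the estimator refuses shorter inputs rather than returning an unstable
number. For uncoupled signals the PLV does not vanish but concentrates
around the chance floor of a mean of `N_eff` uniform phasors
(≈ `sqrt(pi / (4 N_eff))` with `N_eff` the number of independent slow
cycles); a 60 s epoch sits well below 0.15. Per-animal values average
the valid electrodes. An optional diagnostic, `plv_shuffle_null()`,
recomputes the PLV after randomly permuting the envelope in time —
note that a *circular shift* would be a broken surrogate here, since
shifting a periodic envelope preserves perfect locking at a different
lag.

## The synthetic signal model

`generate_coupled_lfp()` produces

```
x(t) = A_th sin(2π f_th t)
     + A_g (1 + κ cos(φ_th(t) − ψ0)) / (1 + κ) · sin(2π f_g t)
     + pink(t) + line(t)
```

where `φ_th` is the Hilbert-convention phase of the theta component, so
the estimator should recover ψ0 exactly. The `(1 + κ)` normalisation
pins the envelope maximum rather than its mean, keeping gamma power
approximately κ-invariant — coupling strength and band power are
independently controllable, mirroring experiments in which coupling
changes without power changes and vice versa. Pink noise is spectrally
shaped white noise with power ∝ 1/f and no power below 1 Hz (the
hardware high-pass edge); line noise is a family of fixed-frequency
sinusoids with random phases. Everything is deterministic given the
seed.

Defaults (7 Hz / 50 µV theta, 75 Hz / 10 µV gamma, 20 µV pink noise
where noise is on) give theta-dominated spectra with gamma clearly above
the in-band noise floor, a realistic regime for cortical LFP.

What the generator deliberately does *not* emulate: non-sinusoidal
theta waveform asymmetry (a known source of spurious coupling in real
data), movement and chewing artifacts, non-stationarity across an
epoch, volume conduction between electrodes, and state transitions.
Passing tests therefore demonstrate estimator correctness on the stated
signal class, not robustness to every pathology of in-vivo data.

## Synthetic cohorts

`generate_cohort()` emulates the design of a drug experiment: each
animal's parameters (theta and gamma amplitudes, coupling strength) are
drawn once from lognormal between-animal variability (σ = 0.2) and
shared between that animal's baseline and post epochs; treatment enters
only in the post epoch as per-group multipliers on low-gamma power,
high-gamma power and κ. The default cohort mirrors a three-group
design with unequal n (7/5/5). The default treated-group effects —
low-gamma power × 1.5 and κ × 0.25, identical in both treated groups —
encode the qualitative phenotype of NMDA-receptor antagonism (elevated
low-gamma power, disrupted theta–high-gamma coupling); no quantitative
effect sizes exist to copy, so these magnitudes are free parameters of
the simulator, documented as such and fixed.

Cohort epochs default to 60 s at fs = 500 Hz: over 400 theta cycles per
epoch for stable PLV estimation, a 250 Hz Nyquist comfortably above the
100 Hz analysis edge, and cheap enough that power experiments over
dozens of replica cohorts are routine. A deliberate estimator-level
side effect worth knowing about: raising an oscillation's amplitude
also raises its envelope's signal-to-noise ratio, so a power
manipulation can shift measured PLV for that band even at fixed κ —
visible in theta–low-gamma PLV when low-gamma power is multiplied.

## Behavior

**Frames.** The arena rotates by `θ(t) = 2π t / rotation_period`
(counterclockwise by default; the direction is configurable as it is
purely a sign convention). Arena→room is rotation by `+θ(t)`,
room→arena by `−θ(t)`; the transform preserves radius exactly and
round-trips to machine precision. Distance on the carousel is reported
in both frames: the arena frame measures locomotion net of passive
transport (a disc-fixed point travels 2πr per revolution in the room
frame but 0 in the arena frame) and is the more behaviorally meaningful
number; the room-frame value is also available since the original
frame convention for reported distances is not fixed by convention in
the field.

**Entrances and shocks.** An entrance is a maximal interval with
room-frame azimuth inside `sector_center ± sector_halfwidth` (60°
sector by default). The hysteresis `min_outside` defaults to 0 — every
exit ends an entrance — because no debouncing rule is standard; it is
configurable for noisy trackers. Shocks are instantaneous events: one
at entrance onset and one per 900 ms of continuous occupancy, i.e. a
dwell `d` earns `#{k ≥ 0 : 0.9 k < d}` shocks (a 10 s dwell earns 12).
These definitions reproduce exact combinatorial oracles: a disc-fixed
point at 30 cm radius sweeps the sector once per 60 s revolution,
giving 20 entrances of 10 s and 240 shocks in a 20-min session.

**Open field.** The centre zone is the concentric square containing
`center_zone_fraction` of the box area (default 0.25 → a 35 cm square
in the 70 cm box). "Centre" has no universal definition; a quarter of
the area is a common choice and the fraction is exposed. Path length
sums Euclidean steps after optional running-median smoothing, ignoring
steps below `jitter_floor`; with a 0.5 cm floor, tracker jitter of
0.1 cm SD around a stationary animal contributes essentially nothing.

**Walk simulator.** Locomotion is an Ornstein–Uhlenbeck velocity
process (persistence time 1 s) reflected at the boundary, with the
per-component stationary SD set so the Rayleigh mean speed equals
`mean_speed`. Sector avoidance is the simplest mechanism that yields an
entrance-count dose response: inside the sector dilated by 15°, a
tangential acceleration of magnitude `avoidance_gain` pushes the walker
out of the nearer edge.

## Statistics

The gated chain is: Shapiro–Wilk per group (parametric iff every group
passes at α = 0.05), then one-way ANOVA with Tukey HSD or
Kruskal–Wallis with Dunn z-tests; post hocs run only on a significant
omnibus. Conventions that are not universal and therefore fixed
explicitly here: Tukey uses the studentized range with the
Tukey–Kramer correction (the designs of interest have unequal n); Dunn
p-values are Bonferroni-adjusted over all pairs by default with Holm
available; the Kruskal–Wallis H is tie-corrected. Degenerate inputs are
errors or defined values, not silent numbers: constant groups fail the
gate, zero within-group variance with unequal means reports an infinite
F flag, complete ties give H = 0.

The balanced repeated-measures two-way ANOVA (group between, day
within, subjects nested in group) is provided as a convenience for
complete designs only, without sphericity correction — incomplete or
unbalanced tables are redirected to proper mixed-model tooling rather
than silently mis-analysed.

## Verification strategy and problem sizes

Every stage is tested against constructions with independently known
answers: Parseval identities for the PSD; analytically designed sines
for filter gain and phase; the generator's own ground truth for PAC
(full coupling ⇒ PLV ≥ 0.95 with ψ0 recovered; uncoupled 60 s epochs at
the chance floor; mean PLV strictly increasing over
κ ∈ {0, .25, .5, .75, 1} averaged across 20 seeds); closed-form
geometry for the arena (circumference paths, sector sweeps, shock
counts); and brute-force evaluation of the F and H defining formulas to
1e-10 on random small tables. Calibration of the inferential chain uses
1000 null simulations at group sizes 7/5/5, and the end-to-end check
runs dozens of seeded replica cohorts at the documented effect sizes,
requiring the programmed effects to be detected with high power while
all-null cohorts reject near the nominal 5 %. These problem sizes
(60 s epochs, 10–50 seeds per condition) were chosen as the smallest
that keep Monte-Carlo error well below the margins being asserted.

## Known limitations

- Epoch rejection / artifact handling is out of scope; epochs are
  assumed clean.
- The PLV is the only coupling estimator (no modulation index or
  GLM-PAC, no comodulogram scans); band pairs are fixed by
  configuration.
- EDF and proprietary acquisition formats are not read; the interchange
  formats are CSV/float32 + JSON sidecar.
- The shuffle surrogate destroys all temporal structure of the
  envelope, making it a generous null; block-preserving surrogates
  would be needed for formal single-recording inference, which the
  package intentionally does not offer (group statistics are the
  inferential unit).
- The walk simulator produces statistically plausible but not
  behaviorally learned trajectories: avoidance is a fixed drift, not a
  learning process, so across-day learning curves are outside its
  scope.
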