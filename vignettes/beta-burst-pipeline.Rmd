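---
title: "Attention-modulated beta bursts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-modulated beta bursts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmburst)
```

# The scientific problem

Beta-band (13–30 Hz) activity in sensorimotor cortex is not a sustained
oscillation but a train of transient, punctate *bursts*, and its amplitude
drops both during tactile stimulation and — more subtly — when covert
attention is directed to the corresponding hand. `opmburst` implements a
complete source-space analysis chain for testing that attentional
modulation in wearable optically-pumped-magnetometer (OPM) MEG recordings:
a braille tactile-attention paradigm, a ground-truthed synthetic OPM-MEG
generator, sensor-space quality control with homogeneous field correction,
LCMV beamformer virtual electrodes, Hilbert-envelope contrast-to-noise
ratios (CNR), burst detection by a univariate time-delay-embedded (TDE)
3-state Gaussian hidden Markov model (HMM), and across-subject Wilcoxon
sign-rank contrasts under Benjamini–Hochberg (BH) false-discovery-rate
control.

Human recordings are not bundled; the synthetic module is a first-class,
tested component that generates every input the analysis consumes, with
ground truth retained so each stage can be validated quantitatively.

# The paradigm

A trial lasts 16 s: a target braille pattern is presented bilaterally in
the 1–3 s window; a visual cue (left/right arrow) in the 4–6 s window
directs attention to one hand; five 260 ms probe stimuli follow at 7 s,
spaced 1.1 s apart, each pseudo-randomly assigned to a hand. Five fixed
patterns are used, each with exactly 4 of 8 pins raised. The number of
target-pattern presentations on the attended hand is drawn from a
gamma(shape 4, scale 0.3) distribution, rounded and clipped to the five
probe slots (counts must be integers in 0..5; the discretisation is our
choice). Eighty task trials are recorded with one 16 s rest trial after
every ten; only a 16 s rest length closes the schedule at the printed
1408 s total, so that is what the generator uses. Cue order is a seeded
uniform permutation of a balanced label vector; non-target probe hands are
independent fair coins; target probes sit on the cued hand by definition.
All windows are half-open `[a, b)` with onset sample `round(t * fs)`.

```{r schedule}
sched <- generate_schedule(80, 10, seed = 1)
sched$total_duration_s
table(sched$trials$cue)
```

# The synthetic OPM-MEG generator

**Geometry and forward model.** Triaxial sensors (one radial, two
tangential axes) are placed quasi-uniformly on an upper hemisphere of
radius 0.12 m; sources are labelled region centroids strictly inside a
homogeneous conducting sphere (radius 0.09 m). Fields are computed with
the closed-form current-dipole solution for the spherical conductor. This
deliberately replaces anatomy-dependent single-shell models: it is exact,
fast, and preserves the properties the pipeline relies on (radial sources
are silent; the field depends only on the tangential moment), at the cost
of realism in sensor topographies. Source orientations are therefore
random *tangential* unit vectors.

**Burst dynamics.** Each somatosensory region emits an inhomogeneous
Poisson train of oscillatory packets riding on a 1/f background
(sd 0.3 source units). A packet is a Tukey(0.5)-windowed arc-shaped
waveform: an alpha-band fundamental (9–12 Hz, random frequency and phase
per burst) plus its *phase-locked* second harmonic at weight 0.6, the
classic non-sinusoidal shape of the sensorimotor mu rhythm. That locking
matters: with an independently-phased beta component the within-burst
waveform is non-stationary in lag space and no single HMM state can
represent a burst; the harmonic waveform reproduces the pan-spectral burst
spectrum (alpha peak, beta shoulder) as a single repeating motif. Burst
durations are log-normal (median 0.25 s, sdlog 0.4); the baseline rate is
2 bursts/s. During stimulus delivery to a region's hand the rate is
multiplied by 0.6; throughout the cue and probe windows of trials where
that hand is attended it is additionally multiplied by 0.75. These rate
and effect values are our calibration — the defaults produce a ~20%
relative modulation of burst probability, the magnitude of attentional
effects the method is meant to resolve — and are configuration fields, not
asserted facts about any real recording.

**Sensor model.** White noise is parameterised as an amplitude spectral
density of 10 fT/√Hz (a realistic OPM floor, deliberately below the 16
fT/√Hz bad-channel ceiling) so the floor is invariant to the simulation
rate; uniform interference is three independent random walks band-limited
below 2 Hz (sd 5 pT per axis) projected onto every channel axis — exactly
the component homogeneous field correction models. The source moment
scale is 5 nAm.

# Preprocessing

Welch spectra (2 s Hann segments, 50% overlap by default) feed a
bad-channel rule: median amplitude spectral density above 16 fT/√Hz in
5–150 Hz, or an identically zero spectrum. The median was chosen over the
mean for robustness to line-noise spikes. Trials (including rest blocks)
are rejected when their pooled standard deviation exceeds 3 times the SD
of all data combined; pooling over channels and samples keeps the rule
scale-invariant (a per-channel variant would change decisions under
channel-dependent gains). Homogeneous field correction projects the data
onto the orthogonal complement of the channels-by-3 matrix of measurement
axes; the same projector is applied to every lead field downstream, so
that the beamformer's unit-gain constraint lives in the corrected space —
omitting that step lets the weights put arbitrary mass in the removed
subspace.

# Beamforming

Covariances are estimated per band (1–48 Hz broadband, 13–30 Hz beta,
4th-order zero-phase Butterworth) over all samples surviving trial
rejection — rest blocks included, since the contrasts need rest-calibrated
baselines (a flag excludes them if desired). Each covariance is
regularised by adding 5% of its largest eigenvalue to the diagonal. The
source orientation is the unit vector maximising beamformer output power,
i.e. the minimum eigenvector of `L' C⁻¹ L` restricted to the subspace
where the lead field is non-null (the spherical model's radial direction
is excluded automatically; a minimum lead-field-norm guard rejects
degenerate regions where the power criterion would otherwise chase noise).
Weights are the classic unit-gain LCMV solution computed via Cholesky
factorisation; no explicit inverse is formed.

# Envelopes and CNR

The beta-band virtual electrode is Hilbert-transformed *once over the
whole recording* before any epoching (edge effects are confined to ~0.5 s
at each end, which no trial window touches). Baseline mean and SD come
from the last 8 s of every kept rest trial; CNR is
`100 × (env − μ_b) / σ_b`, i.e. change from baseline in units of baseline
SD, in percent. Trials are averaged within cue condition; probe epochs
(−180 ms to +650 ms) are split into attended/non-attended by stimulated
hand, with target probes and incorrect-response probes excluded (synthetic
subjects press incorrectly at a configurable 5% rate so the exclusion path
is genuinely exercised), and counts equalised by seeded random discard
within each stimulated hand.

# Burst detection

The 1–48 Hz virtual electrode is downsampled to 100 Hz (anti-aliased),
z-scored, and embedded with 15 centred lags (±70 ms) — values from the
TDE-HMM burst literature; the model itself is silent on them — then
reduced to 6 principal lag components. A 3-state Gaussian HMM is fitted by
maximum-likelihood EM (Baum–Welch) with seeded k-means restarts, the best
converged log-likelihood winning. Two observation-model choices matter:

* **Zero-mean emissions.** State means are fixed at zero so states differ
  only in autocovariance. With free means, EM splits an oscillation's
  phase ring into two antipodal-mean states that alternate every half
  cycle, and no single state tracks bursts.
* **Covariance flooring.** State covariance eigenvalues are floored at
  10⁻⁶ times the data variance to prevent collapse.

EM is used instead of the variational Bayesian machinery common in this
literature: at this model size the state-decoding semantics are identical
and the likelihood can be verified exactly against an exhaustive
path-enumeration oracle. Parameters are estimated on the leading portion
of the embedded series (400 s by default) and the whole recording is then
decoded in one forward–backward pass; 40 000 embedded samples are ample
for 3 full-covariance states in 6 dimensions.

Posteriors are binarised at 2/3 (threshold above 1/2, so states are
mutually exclusive after binarisation); the *burst state* is the one whose
binary time course correlates highest with the beta envelope (ties resolve
to the lowest index with a warning; a flag switches the correlation to the
posterior instead of the binary course). Burst events are maximal runs of
ones; their amplitude is the maximum of the 1–48 Hz Hilbert envelope at
the state grid rate within the run. Burst probability is the fraction of
a condition's trials with the burst state active at each trial-relative
time point. Burst counts within the cue (4–6 s) and probe (0–1.1 s)
windows require full encapsulation — a burst must start *and* end inside
the window. State-wise spectra are multitaper (DPSS, time-bandwidth 3,
5 tapers, 1 s windows) periodograms averaged with per-window state
occupancy weights; a never-active state yields an `NA` spectrum rather
than a fabricated one.

# Statistics

Per-subject condition means enter Wilcoxon sign-rank tests across
subjects: exact two-sided p-values by full sign-flip enumeration (midrank
ties handled exactly) for up to 25 effective pairs, a tie-corrected normal
approximation with continuity correction above. Zero differences are
dropped before ranking, the standard convention. Two families are
corrected separately at q = 0.05, mirroring the two correction rounds of
the analysis design: 4 envelope tests (CNR × cue/probe window ×
hemisphere) and 12 burst-metric tests (count, amplitude, duration ×
window × hemisphere). Tests are two-sided despite directional predictions;
the effect direction is reported alongside.

# Problem sizes for validation studies

The simulation studies shipped in the test suite and driven by
`scripts/acceptance.R` use `desk_config()`: the full 80-trial, 1408 s
paradigm per subject at 200 Hz with 12 triaxial sensors, 4 source regions,
and a lighter HMM schedule (fit on the first 120 s of embedded samples,
2 restarts, 25 EM iterations), with 8 subjects per cohort. These sizes are
the package's choice of desk-scale problem; every scientific parameter
(trial structure, bands, thresholds, rejection rules, FDR level) is
identical to `default_config()`, which runs at the full 1200 Hz / 32
sensor / 8 region profile.

# What the synthetic data do and do not show

The generator reproduces the features the pipeline's claims rest on:
trial-locked condition-dependent burst rates, pan-spectral arc-shaped
packets, uniform-field interference and a white sensor floor, behavioural
errors, and spherical-conductor physics. It does not emulate anatomy or
co-registration error, correlated sensor noise, movement, heartbeat or
ocular artefacts, inter-subject variability in burst morphology, or
volume-conduction differences from realistic head shapes. Passing tests
therefore demonstrate that the pipeline recovers the effects it is built
to detect under its own stated assumptions — not that those assumptions
exhaust real OPM recordings.

# Known limitations

* The spherical conductor makes radial sources invisible; orientations
  are searched only in the tangential plane.
* A single HMM is fitted per region and subject; no group-level or
  multivariate state model is attempted.
* Bursts that are pan-spectral cannot be decomposed into alpha-only and
  beta-only constituents by this method.
* The post-stimulus beta rebound is not modelled or analysed; the probe
  spacing never lets it evolve.
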