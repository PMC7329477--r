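---
title: "Methods: simulating and analysing 40 Hz auditory steady-state MEG responses"
author: "assrpipe developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing 40 Hz auditory steady-state MEG responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Periodic "clicktrain" stimuli (here 2 ms clicks every 25 ms for 1.5 s)
entrain neural populations in primary auditory cortex (A1) at the click
rate, producing an auditory steady-state response (ASSR) that is strongest
at 40 Hz, alongside a transient broadband 30–60 Hz burst (tGBR) within
~0.1 s of stimulus onset. Group differences in the ASSR — in oscillatory
power and in inter-trial phase coherence (ITC) — are a candidate marker of
dysregulated gamma-band circuitry, for example in autism-spectrum cohorts.
`assrpipe` provides a complete, testable re-implementation of the standard
MEG analysis chain for this paradigm, together with a synthetic-data
generator whose ground truth lets every stage be validated: because the
underlying human recordings for studies of this kind are typically not
shareable, the package's claims are checked against simulation and
closed-form anchors rather than archived data.

# The generative model

Each subject is a pair of tangential current dipoles at geometric
stand-ins for left and right A1 inside a spherical head conductor
(radius 0.09 m). Per trial, each source emits

* a **sustained entrained component**
  `A · env(t) · cos(2π · 40 · t + φ(t))` over the 1.5 s train, with a
  raised-cosine onset/offset ramp (50 ms). The trial phase `φ` is drawn
  from a von Mises distribution with concentration `κ`: `κ = ∞` is
  perfect phase locking, `κ = 0` uniform phase. `φ(t)` cross-fades
  (raised cosine, 0.1 s wide) from an early-period draw to an independent
  late-period draw with concentration `κ_late` at 0.5 s, so phase
  consistency can change mid-trial without a discontinuity;
* a **transient burst**: Hann-windowed 30–60 Hz band-limited noise over
  0–0.1 s, RMS-calibrated to its dipole moment.

The von Mises choice is deliberate: its mean resultant length
`I₁(κ)/I₀(κ)` is the closed-form expected ITC, giving an analytic ground
truth for phase-consistency recovery (`vm_mean_resultant()`).

Sensor data are the forward projection of these moments plus 1/f
background activity from 30 randomly placed interior dipoles and white
sensor noise. Defaults (15 nA·m sustained, 25 nA·m burst, κ = 4,
5 × 10⁻¹² T/m sensor noise, 8 nA·m background dipoles) were chosen once so
that a single subject's trial-averaged virtual electrode shows an
unambiguous ASSR and the two-group pipeline detects the default group
effect — the same calibration philosophy a power analysis would use.

## Group effect templates

The two-group generator applies per-group templates. The default "ASD"
template multiplies the sustained amplitude by 0.6 and halves `κ` for the
period after 0.5 s, leaving the 0–0.1 s burst untouched; the control
template is the identity. One parameterisation therefore produces both the
power and the ITC group phenomenology, with a known effect onset for
window-recovery tests.

## Inter-subject heterogeneity

Every subject additionally receives two lognormal factors (sdlog 0.2): a
response gain on both source amplitudes and a noise gain on the sensor and
background noise levels. This is not cosmetic. With perfectly identical
"clone" subjects we observed that the subject-specific common beamformer
filters transmit the groups' 40 Hz power difference into the
transient-gamma percent change (the 30–60 Hz covariance window contains
40 Hz, so group membership perturbs each subject's filter and with it the
virtual-electrode noise floor); with near-zero within-group variance this
microscopic bias produced large spurious t values in a contrast whose
generating parameters are identical. Real cohorts are protected by
inter-subject variability, and so is the simulated one. Setting
`subject_variability = 0` reproduces the degenerate behaviour.

## What the generator does not emulate

Head-position differences and movement, Maxfilter/tSSS residuals,
eye/muscle artifacts, anatomical variability (one sphere and one helmet
for all subjects), ear-specific acoustics, evoked (M100-style) components,
and any built-in brain–behaviour coupling (behavioural scores are drawn
independently of the brain effect; correlations are expected null). A
green end-to-end test therefore establishes that the pipeline recovers the
stated effects under this idealised but structurally faithful world — not
that it is robust to every artifact of real recordings.

# Forward model

The spherical-conductor closed form for the external field of a current
dipole replaces a realistic single-shell model. It is analytic and
dependency-free, and preserves the properties the pipeline relies on:
linearity and superposition, decay with distance, and the silent radial
orientation (the source-orientation search below excludes that degenerate
direction). This is the package's one deliberate physics simplification;
positions are metres, moments nA·m, fields Tesla (magnetometers) or
Tesla/m (planar gradiometers, modelled as two-point finite differences
with a 16.8 mm baseline). The default array places 102 sites
quasi-uniformly on the upper hemisphere, two orthogonal planar
gradiometers each; only gradiometers are used by default. The source space
is a volumetric grid (10 mm default) rather than a cortical mesh; "A1"
ROIs are all grid vertices within 15 mm of canonical bilateral positions
(±52, −20, 20) mm.

# Preprocessing

Butterworth filters are designed as second-order sections (analytic
prototype, bilinear transform) and applied forward–backward (zero phase),
with reflection padding scaled to three time constants of the slowest
band edge. The broadband filter is the cascade high-pass order 3 at
0.5 Hz and low-pass order 4 at 250 Hz — the literal reading of the
acquisition convention — plus band-stops at 49.5–50.5 and 99.5–100.5 Hz.
Epochs span −2 to +2 s (±1.5 s analysis window plus 0.5 s padding);
each trial is linearly detrended. Trial rejection summarises each trial's
per-channel variance by its maximum over channels (the sum is recorded
too, since either reading of a "trial-by-channel variance screen" is
defensible); the absolute-threshold mode is exposed, but the default is
`median + 8 × MAD` because synthetic units need not sit on a Tesla scale.
Resampling to 200 Hz decimates after a zero-phase order-8 anti-alias
low-pass at 0.8 × the new Nyquist; rates that would alias the 35–45 Hz
band are refused.

# Beamforming

Covariance is the trial-averaged second-moment matrix of non-averaged
band-passed data pooled over −1.5 to 1.5 s (pooling baseline and stimulus
gives the "common filter": the same weights are applied to both windows,
never re-estimated per window). Regularisation is diagonal loading with
5% of the mean diagonal. The scalar LCMV filter at each vertex uses the
max-output-power orientation: the leadfield's numerically silent
direction is removed by SVD and the orientation minimising
`uᵀLᵀC⁻¹Lu` is taken in the remaining subspace; then
`w = C⁻¹l / (lᵀC⁻¹l)`, unit gain by construction. Separate ASSR
(35–45 Hz, order 5) and tGBR (30–60 Hz) filter banks are built and tagged
so they cannot be interchanged silently.

ROI collapse: the ROI's vertex filters are stacked, right-multiplied by
the sensor covariance, and the leading principal component (right
singular vector) of that matrix is the ROI weight vector, sign-aligned
with the mean ROI filter. We validated this choice against the obvious
alternative — recombining the unit-gain vertex filters with
PCA-derived weights — on matched subject pairs differing only in the
group template. The covariance-weighted construction preserves the late
amplitude deficit; every unit-gain recombination flattens it, because a
minimum-variance electrode raises its noise gain in proportion to the
interference it must suppress, and with bilaterally phase-correlated
sources that interference scales with the very amplitude under study, so
percent change self-normalises. A corollary of the chosen construction
is that a one-vertex ROI returns its filter in the covariance metric
(`C·w`), not `w` itself. Broadband 0.5–250 Hz data multiplied by the ROI
filter give the virtual electrode.

A note from validation: at extreme SNR with a source that does not
coincide with a grid vertex, LCMV partially cancels the true source while
honouring unit gain at the mismatched vertex — the classic
mismatch-cancellation effect. At realistic noise levels the percent-change
maps peak within one grid step of the true sources; the tests encode both
regimes.

# Time–frequency analysis and ITC

Sliding-window multitaper estimation uses DPSS tapers from the tridiagonal
eigenproblem. The steady-state analysis uses 0.5 s windows stepped by
0.02 s with ±5 Hz smoothing: time–bandwidth product 2.5, hence
`K = floor(2TW) − 1 = 4` tapers (standard multitaper practice; only the
smoothing is externally specified). Window centres use the epoch padding
so the full −1.5 to 1.5 s span is covered; a window that would leave the
padded epoch is an error, never a silent truncation. Per-taper complex
coefficients are retained. Power is calibrated so a unit sinusoid at a bin
frequency reports `amplitude²/2`: with unit-norm tapers the scale is
`2 / mean_k (Σ_t w_k)²` (odd tapers have zero window sum and contribute
nothing at the line frequency; the constant absorbs that). Percent change
is computed after band-averaging (the literal order of the reference
analysis), against the mean over baseline window centres. The frequency
grid is integer Hz; finer grids change nothing at ±5 Hz smoothing.

The transient-gamma statistic averages 30–60 Hz power over 0–0.1 s versus
the preceding 0.1 s. The steady-state 0.5 s window cannot resolve that
contrast — both windows are then dominated by steady-state leakage — so
the transient branch has its own multitaper spec: 0.2 s windows with
±10 Hz smoothing (K = 3), the field's usual trade-off for brief broadband
bursts. The 0.5 s window also fixes the temporal resolution of every
cluster edge to ±0.25 s; reports annotate this.

ITC is the magnitude of the trial-mean unit-normalised coefficient,
computed per taper then averaged over tapers (this preserves the [0, 1]
range and the uniform-phase null used in tests; trials with an exactly
zero coefficient are excluded at that bin with a count). The Z conversion
is the Rayleigh statistic `Z = N·ITC²`, pinned here because the cited
recommendation is a phase-statistics normalisation without a printed
formula; under uniform phases Z is approximately unit-mean exponential.
Band-averaged ITC is Z-converted after averaging (the alternative,
Z-then-average, rescales but does not reorder subjects at fixed N).

# Cluster statistics

Two-stage cluster permutation on 1-D time courses: pointwise two-tailed t
tests (pooled variance; paired variant for vs-baseline contrasts, each
time point against the subject's own baseline-window mean), clusters as
maximal runs of adjacent same-sign suprathreshold samples at α = 0.05,
cluster statistic max-t (the stated choice; summed-t cluster mass is
implemented as an option), and a permutation null of the largest
same-tail cluster statistic over 10,000 label randomisations, with
significance at p < 0.025 per tail. Monte-Carlo p-values use the +1 rule
with the observed labelling included; designs with fewer unique
relabellings than requested permutations switch to exact enumeration.
Ties count as extreme. Adjacency is temporal only.

# Planned contrasts and behaviour

Per ROI: within-group power and ITC versus baseline (sign-flip
permutation), between-group power and ITC Z (label permutation), and a
between-group t test on the scalar transient-gamma percent change. Brain
measures entering Pearson correlations with AQ/GSQ scores are averaged
over the pipeline's own significant between-group windows (power pooled
across ROIs, ITC Z per ROI), falling back to the full stimulus window —
flagged — when no window is significant; correlations are computed for
the ASD group only. Behavioural scores are normal draws from the
configured group means/SDs clipped to the instrument ranges (AQ /50,
GSQ /168). The printed t statistics of the reference demographics are not
recoverable from its printed means/SDs by the pooled formula, so the
package treats those means/SDs as generator parameters and asserts
separation, not specific t values.

# Numerical and engineering choices

* No HDF5 binding is assumed: the epochs container is a directory with
  `meta.json` (times, rate, channel table, provenance) and a little-endian
  float64 `data.bin`, mirroring the intended HDF5 dataset layout.
* Butterworth design, DPSS tapers and the von Mises sampler
  (Best–Fisher) are implemented in-package (no `signal`/`gsignal`
  dependency); the filter designs were cross-checked against an
  independent implementation during development, and the test suite pins
  their transfer functions analytically.
* Zero-phase filtering squares the magnitude response; stated orders
  refer to the one-pass design.
* The per-subject preprocessing has a fused fast path (one samples-major
  reshape) that the tests verify against the modular chain.
* Study configs are JSON; every run echoes config, seeds and package
  version into its outputs. Seeds derive from a master seed by a
  counter-based map, so any subject can be regenerated in isolation.

# Known limitations

Sphere-plus-grid geometry (no anatomy, no coregistration error), a single
shared helmet, temporal-only cluster adjacency, integer-factor
resampling, and a generator whose inter-subject variability is a
two-parameter lognormal rather than an empirical distribution. The
transient-gamma null contrast retains a small residual filter-mediated
group bias at the default heterogeneity (see above); it is dominated by
between-subject variance at realistic settings but measurable in the
clone limit.
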