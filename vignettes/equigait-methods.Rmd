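---
title: "Methods: canter limb-role comparison with motion capture, sEMG and 1D SPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canter limb-role comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In canter the two limbs of each fore- and hindlimb couplet play different
roles: the trailing limb strikes first and the leading limb reaches
further, and both kinematics and muscle activation differ between the
roles. `equigait` compares leading and trailing limbs within horses,
using synchronized marker trajectories and surface EMG collected from the
right limbs in both canter leads (the right limbs are leading in
right-lead canter and trailing in left-lead canter, so each horse serves
as its own control).

Two families of outcomes are compared:

* discrete per-stride variables — stride duration, stride velocity,
  fore/hind stance duration, ARV, burst onset/offset/duration, peak
  timing — with a within-subject linear mixed model;
* continuous stride-normalized waveforms (joint angles, joint angular
  velocities, pro-retraction angles, %RVC envelopes), 101 points per
  stride cycle, with paired-sample one-dimensional Statistical
  Parametric Mapping.

## Kinematic processing

Marker trajectories (mm; laboratory y = direction of travel, z =
vertical) are gap-filled by cubic spline for occlusions of at most 10
frames — longer gaps stay missing and the trial is rejected if an
analysed window retains missing samples — then low-pass filtered with a
zero-phase 4th-order Butterworth at 12 Hz. All filters in the package
run forward and backward: event timing and waveform comparisons live on
a common stride clock, so phase lag is unacceptable; the doubled
effective order is accepted. The filter routine removes an
endpoint-matched line and pads by odd reflection before filtering, which
suppresses the start/end transients that a plain forward-backward pass
produces on trended signals such as a marker translating several metres.

Sagittal joint angles come from a rigid-segment model (two markers per
segment). Each segment frame takes its longitudinal axis from the marker
pair and its x-axis from the laboratory lateral direction; the relative
rotation of adjacent segments is decomposed with the cardan sequence
x, y, z and flexion/extension is the rotation about x. A per-joint sign
makes rotation towards the flexor side positive (flexor side caudal for
shoulder, carpus, stifle, MCPJ, MTPJ; cranial for elbow, hip, tarsus).
Angles are referenced to each horse's static standing trial, so curves
are changes from the standing posture and conformation differences
cancel. Angular velocity is the central-difference derivative.
Pro-retraction is the signed sagittal angle between the limb axis
(scapular spine or tuber coxae to the lateral hoof-wall marker) and the
downward normal of a trunk reference axis from the tubera sacrale to a
virtual point directly above the scapular spine marker; positive is
protraction.

Hoof events use a speed-threshold rule: within each cycle (between
successive swing-speed peaks), impact is the first sustained (≥ 25 ms)
drop of the hoof-marker sagittal speed below 5% of the preceding swing
peak, lift-off the first sustained rise above 5% of the following peak;
the crossing instant is refined by linear interpolation between samples.
The published detector this stands in for is cited but not described in
the source literature available to us, so this implementation is
documented as a stand-in, its thresholds are configurable
(`speed_frac`, `min_dur_s`), and it is validated against the synthetic
generator's ground truth (recall 100%, timing error well under one
232 Hz frame). Strides run from one right-hind impact to the next
regardless of limb role; strides without a complete forelimb stance are
dropped and counted. Stride velocity is the mean y-derivative of the
tubera sacrale marker over the stride.

## sEMG processing

Raw channels (volts, 2088 Hz) are mean-subtracted, high-passed at 40 Hz
(zero-phase 4th-order Butterworth, targeting movement artefact), and
full-wave rectified. Per-stride ARV is the mean rectified value over the
stride window. ARVs are screened per horse and muscle with Tukey fences
(1.5 × IQR; the method cited for this step in the source literature is
unpublished, so the fence rule is a documented stand-in) and normalized
to the surviving maximum, which maps to exactly 100%. Envelopes are
zero-phase low-passes of the rectified signal: 25 Hz for the continuous
%RVC waveform, 10 Hz for peak timing. The RVC is the maximum envelope
value across a horse-and-muscle's strides after screening the
per-stride peaks with the same fence rule; screened strides are still
normalized and may exceed 100%.

Burst detection is the double-threshold scheme: the amplitude threshold
is 5% of the peak of the rectified signal itself, while region finding
runs on the 25 Hz envelope (configurable to raw-rectified). The
amplitude threshold must reference the raw rectified peak: the peak of a
stochastic EMG burst sits ≈ 3–4 × above its plateau RMS, so 5% of it
lands comfortably above the post-filter noise floor, whereas 5% of the
envelope peak would sit below the baseline at realistic SNR and the
detector could never separate bursts. Sub-threshold gaps shorter than
the timing threshold (5% of the cohort mean stride duration) are
bridged, then regions shorter than the timing threshold are discarded —
standard double-threshold semantics, adopted because the cited
description of the gap handling is not available. Bursts are assigned to
the stride containing their midpoint; onsets falling before the stride
boundary are reported modulo 100, and when a muscle's onsets straddle
the boundary (some above 80%, some below 20%) the low ones get +100 so
all onsets share a continuous scale (1.8 → 101.8). The longest burst per
stride is the main burst; the composite-stride diagram draws a muscle's
bar as "intermittent" when a main burst appears in at most half the
strides (the source figure distinguishes the two without a numeric
rule; 50% is our documented default).

## Statistics

Discrete variables: `value ~ limb_role + (1 | horse)` by REML with
Satterthwaite degrees of freedom (`lme4`/`lmerTest`). On a balanced
design collapsed to horse means this reproduces the paired t-test
exactly, which the tests assert to 1e-6; the reported estimate is the
second factor level minus the first (alphabetical, e.g. Tr − Ld). No
multiple-comparison adjustment is applied across variables, mirroring
the presentation style of the field. Singular random-effect fits (zero
between-horse variance) are accepted silently — they occur legitimately
under the null.

Waveforms: each stride curve is linearly interpolated onto 101 points
spanning the stride; the analysis unit is the per-horse mean curve per
condition (a paired design across n horses; per-stride pooling is
deliberately not offered as a default because strides within a horse are
not exchangeable across horses). The paired t-field is the node-wise
paired t statistic, df = n − 1. Residual smoothness is estimated from
variance-normalized residual curves as FWHM = sqrt(4 ln 2 / mean λ),
with λ the per-node variance of the residual gradient taken by central
differences (one-sided at the ends). Central differences were chosen as
the gradient estimator up front: for unsmoothed white residuals the
estimator then converges to ≈ 2.3 nodes, consistent with the ≈ 2-node
behaviour expected of unsmoothed noise, and it recovers the kernel FWHM
of synthetically smoothed fields without bias (20 ± 3 at FWHM 20 in the
tests). Resels = (Q − 1)/FWHM with Q = 101.

The critical threshold t* solves E[EC](t) = α/2 (two-sided; both tails
reported in the source setting), with the expected Euler characteristic
of a 1D t-field E[EC](t) = P(T ≥ t) + resels · sqrt(4 ln 2)/(2π) ·
(1 + t²/ν)^(−(ν−1)/2), found by `uniroot` on (0, 100); resels → 0
recovers the ordinary critical t. Suprathreshold clusters are maximal
runs of |t| > t*; cluster p-values use the standard 1D extent
approximation P(extent ≥ k) = exp(−πk²/4η²) in resel units with η the
expected extent per cluster, corrected as 1 − exp(−m·P). Zero-variance
nodes produce ±∞ t-values; they are flagged and clipped to the finite
field maximum for cluster formation. Because the exact internals of the
SPM software used in the source setting are not restated here, a
sign-flip permutation oracle (exhaustive when n_perm ≥ 2^n, otherwise
seeded sampling) is the package's internal ground truth: the tests
require the RFT and permutation thresholds to agree within 10% across a
(df, FWHM) grid, the empirical family-wise error on null cohorts to lie
in [0.03, 0.08] at α = 0.05, and the node-wise t to match the scalar
paired t-test to 1e-10.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions: 10 horses × 2 leads ×
7 strides (≈ 70 strides per lead, the scale of a ridden session), stride
duration 0.59 s with 3% multiplicative jitter and per-horse intercepts,
hind stance 0.32 s, fore stance 0.29 s trailing with a −0.02 s leading
delta injected through `effect_sizes`, stride velocity 4.41 m/s with
multiplicative between-horse (≈ 4.5% CV) and slow within-trial (≈ 2%)
variation, kinematics at 232 Hz and sEMG at 2088 Hz, and the same-side
fore impact at the 55.5% advanced-placement ratio of the hind stance —
so the diagonal LdH–TrF beat sits where the field's timing literature
puts it.

Joint-angle truth is a static posture plus four stride harmonics
(≤ 6.8 Hz, inside the 12 Hz passband), with per-horse amplitude/phase
variation and a smoothly interpolated per-stride gain (knots at stride
midpoints) so stride-to-stride variability never introduces
discontinuities that the filter would ring on. The angle chain is driven
through a planar forward-kinematic linkage, so inverting the marker
geometry recovers the truth exactly up to filter and jitter effects.
Hoof-wall markers are authored directly: stationary during stance
(0.3 mm jitter) and advancing during swing with a speed profile
v₀ + (v_p − v₀)sin²(πu), v₀ = 10% of the peak — the hoof lands with
non-zero velocity and stops abruptly, as real hooves do, which is also
what makes the 5% speed threshold cross at the true event instant. The
generator therefore prioritises exact, well-defined ground truth per
analysis stream over full kinematic-chain consistency: the hoof-wall
marker is not the forward-kinematic chain's distal endpoint (real
recordings simply map both names to the same marker).

sEMG channels are a 20–450 Hz unit-RMS noise carrier modulated by
raised-cosine-edged boxcar envelopes (edge midpoint = true
onset/offset; edge width 3% stride), with per-role burst windows and
amplitude scales taken from published canter activation timing for the
triceps, splenius, gluteal and biceps. Burst windows are deterministic
given the spec — the seed changes sample paths, never the truth. Noise
enters at the requested outside-burst SNR (default 20 dB) split 90/10
between low-frequency (< 35 Hz) movement artefact and a broadband floor,
matching why the 40 Hz high-pass exists in the processing chain.

Not emulated: out-of-plane rotation (x coordinates are constant plus
jitter — the analysis is sagittal), rider and saddle dynamics, ground
reaction forces, skin-motion artefact on markers, electrode lift-off or
cross-talk between muscles, and within-stride onset-timing variability
of the bursts. Passing tests therefore demonstrate the correctness of
the processing and inference machinery under controlled conditions, not
robustness to every artefact of ridden data.

## Numerical choices and degenerate inputs

* Tolerances: event persistence 25 ms; `uniroot` tolerance 1e-10 for t*;
  variance guards at 1e-300 before division; cluster p clamped to
  [1e-16, 1].
* Ties: peak timing takes the earliest argmax (a constant envelope
  reports 0%).
* Degenerate inputs: coincident or lateral-parallel segment markers are
  an error naming the segment; an all-zero ARV set, zero RVC, fewer
  than 2 hind impacts, fewer than 4 strides for outlier screening, and
  fewer than 2 horses with both limb roles are errors; a stationary
  hoof marker yields no events with a warning; constant residuals give
  resels 0; no RFT solution below t = 100 (tiny df with rough fields)
  is an error, which the pipeline logs per variable and skips.
* Determinism: every generator stream derives its seed from the spec
  seed, horse index, lead and stream name (kept within 32-bit range);
  identical specs produce byte-identical datasets and identical
  pipeline re-runs produce byte-identical bundles.

## Problem sizes used by the tests and acceptance script

Recovery checks run on cohorts of 2–10 horses with 3–6 strides per lead;
the family-wise error and power studies use 500 and 200 curve-level
cohorts (10 horses, 6 strides per condition, within-horse smoothness
FWHM 15 nodes — typical of stride-normalized gait curves); the
mixed-model type-I study uses 500 replicates. These sizes give Monte
Carlo standard errors comfortably inside the asserted bands (e.g.
±0.01 on a 0.05 FWER with 500 replicates). Error-rate simulations run at
the curve level rather than through 500 full marker+EMG pipelines; the
inference code under test is identical, and the full pipeline is
exercised end-to-end separately.

## Known limitations

* The hoof-event detector and the ARV outlier rule are stand-ins for
  cited but unavailable method descriptions; both are configurable and
  validated only against synthetic ground truth.
* Cluster p-values use the asymptotic 1D extent approximation; for
  small df and rough fields the permutation oracle is the safer
  reference and is exported for exactly that use.
* The cardan decomposition is implemented in 3D but exercised mainly on
  planar data; real three-dimensional marker sets flow through the same
  code path, with the lateral axis convention documented above.
* Mixed models treat strides as conditionally independent given the
  horse intercept; serial correlation within a trial is not modelled.
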