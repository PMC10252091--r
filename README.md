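# equigait

Comparative biomechanics of the leading and trailing limbs in cantering
horses, as an end-to-end R pipeline. The canter is an asymmetrical
three-beat gait — trailing hindlimb (TrH), then the diagonal pair of
leading hindlimb and trailing forelimb (LdH–TrF), then the leading
forelimb (LdF) — and the two limbs of each fore/hind couplet do
systematically different mechanical work. `equigait` is for gait-analysis
labs that collect synchronized 3D motion capture (≈232 Hz) and surface EMG
(≈2088 Hz) from ridden horses and want a tested, reproducible route from
raw marker trajectories and sEMG channels to limb-role comparisons.

The pipeline implements:

* **Kinematics** — cubic-spline gap interpolation (≤10 frames), zero-phase
  4th-order Butterworth low-pass (12 Hz), sagittal joint angles for the
  shoulder, elbow, carpus, MCPJ, hip, stifle, tarsus and MTPJ from a
  rigid-segment model (cardan sequence x, y, z; flexion/extension about
  the segment x-axis), static-trial normalization, joint angular
  velocities, fore/hind pro-retraction angles against a trunk reference
  axis, hoof impact/lift-off detection from hoof-wall marker speed,
  stride segmentation between successive hind impacts, and per-stride
  spatiotemporal variables (stride duration, stance durations, stride
  velocity from the tubera sacrale marker).
* **Surface EMG** — DC removal, zero-phase 40 Hz high-pass, full-wave
  rectification; per-stride average rectified value
  ARV = (1/T)·∫|x(t)|dt, Tukey-fence outlier screening, normalization to
  the per-horse/muscle maximum; 25 Hz and 10 Hz linear envelopes;
  reference-voluntary-contraction (%RVC) normalization; and
  double-threshold burst detection (amplitude threshold = 5% of the
  signal peak, timing threshold = 5% of the mean stride duration) giving
  stride-relative onset/offset/peak timings, with the +100% wrap
  convention for onsets that straddle the stride boundary.
* **Statistics** — discrete variables compared with within-subject linear
  mixed models, `value ~ limb_role + (1 | horse)`, fitted by REML with
  Satterthwaite p-values; 101-point stride-normalized waveforms compared
  with one-dimensional Statistical Parametric Mapping: the paired
  t-field SPM{t} over per-horse mean curves, residual smoothness
  estimated as FWHM = sqrt(4·ln2 / mean gradient variance) of
  unit-variance residuals, the random-field-theory critical threshold t*
  solving E[EC] = α/2, cluster-extent p-values, and a sign-flip
  permutation oracle for validating the RFT results.
* **Synthetic cohorts** — a generator producing marker + sEMG datasets
  for n horses × 2 canter leads with full ground truth (stride 0.59 s,
  hind stance 0.32 s, fore stance 0.29/0.27 s trailing/leading, 4.41 m/s,
  LdH placed at 55.5% of TrH stance, configurable burst windows, SNR and
  per-variable limb effects), so every stage is testable without ridden
  data.

## Worked example

```r
library(equigait)

spec <- cohort_spec(n_horses = 10, strides_per_lead = 7, seed = 42)
dir <- file.path(tempdir(), "demo")
generate_cohort(spec, dir)                     # markers + sEMG + manifest
res <- run_gait_pipeline(dir, out_dir = file.path(dir, "results"))

subset(res$summaries, variable == "fore_stance_s")
subset(res$comparisons, is.na(muscle))
```

```
      variable limb_role  n  mean     sd
 fore_stance_s       LdF 70 0.269 0.0104
 fore_stance_s       TrF 70 0.288 0.0110

            variable  estimate  p_value
   stride_duration_s  0.002745 2.95e-01
 stride_velocity_mps -0.017795 3.21e-02
       fore_stance_s  0.019681 1.60e-24
       hind_stance_s  0.000666 7.42e-01
```

The cohort was generated with a 0.02 s trailing-vs-leading forelimb
stance asymmetry and none elsewhere; the mixed model recovers the
forelimb effect (estimate is trailing minus leading, 0.0197 s,
p ≈ 2e-24) while stride duration and hind stance stay null. A waveform
comparison returns a classed object with `print`/`summary`/`plot`
methods:

```r
res$spm$angle_carpus
#> Paired 1D SPM [angle_carpus]: n = 10, df = 9
#>   FWHM = 11.41 nodes, resels = 8.77, t* = 4.381 (alpha = 0.05)
#>   no suprathreshold clusters
plot(res$spm$emg_gluteal, labels = c("leading", "trailing"))
```

The carpus angle curves are identical between limb roles by
construction, and the SPM correctly finds nothing; the gluteal %RVC
curves carry a built-in amplitude asymmetry and show suprathreshold
clusters. `res$phasic` holds the composite-stride diagram data, with the
leading-limb bars shifted by 0.555 × the TrH stance duration
(30.75% stride here). A command-line front end over the same functions
is installed at `inst/cli/equigait.R` (verbs `simulate`, `validate`,
`run`).

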