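Package: equigait
Title: Equine Canter Gait Analysis with Motion Capture, Surface EMG and 1D SPM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for comparing leading and trailing fore-
    and hindlimb biomechanics in cantering horses. Turns 3D marker
    trajectories into filtered sagittal joint angles, angular velocities,
    pro-retraction angles, hoof events and spatiotemporal stride variables;
    processes raw surface EMG into per-stride average rectified values,
    reference-voluntary-contraction-normalized envelopes and double-threshold
    activation timings; and compares limb roles with within-subject linear
    mixed models for discrete variables and one-dimensional Statistical
    Parametric Mapping (paired t-fields with random-field-theory thresholds
    and a sign-flip permutation oracle) for 101-point stride-normalized
    waveforms. Includes a synthetic multi-horse canter generator (markers
    plus EMG) with full ground truth so every stage is testable without
    ridden data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
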