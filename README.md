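# megbeamer

Minimum-variance beamformer source analysis of MEG data in R.

MEG sensors measure a superposition of the magnetic fields of many
neural sources. `megbeamer` un-mixes them with spatial filtering: for a
candidate source location with tangential lead-field columns
`L = [l1 l2]` and channel covariance `C`, the scalar minimum-variance
beamformer passes unit gain from that location while minimising output
variance,

    w = C⁻¹ L θ̂ / (θ̂' L' C⁻¹ L θ̂),

with the source orientation `θ̂` chosen to maximise output power (the
closed-form 2×2 eigenproblem of `L' C⁻¹ L`). Scanning `w` over a whole-
brain grid yields source images:

* **ERB** (event-related beamformer): the trial-averaged, phase-locked
  response projected through `w` and noise-normalised —
  `|w'b̄(t)| / sqrt(w' Σn w)`, a rectified pseudo-Z movie across
  latencies;
* **SAM** (synthetic aperture magnetometry): signed images of band-
  limited power change between an active and a baseline window,
  pseudo-T `(Pa − Pb)/(2 w' Σn w)` or pseudo-F `Pa/Pb`, with weights
  from the pooled baseline+active covariance;
* **contrasts** between conditions computed with common (pooled-
  covariance) weights so weight differences cannot masquerade as
  effects.

Around that core the package provides the full chain: an open dataset
container plus CTF-style `.shape`/`.hdm`, OFF/GIfTI and NIfTI I/O;
band-pass and powerline-notch filtering; epoching with automated
peak-to-peak/flat, flux-jump, noisy-channel and head-motion rejection
(from continuous head localization); spherical and per-channel
multi-sphere head models fitted to head-shape points; virtual-sensor
time courses with Morlet time-frequency analysis (total, evoked, and
induced power); group averaging, peak finding, and omnibus sign-flip
permutation thresholds (2048 permutations for 12 subjects). A dipole
simulator generates complete recordings with planted ground truth, so
the entire chain is validated end to end. It is aimed at MEG
researchers who want a scriptable, testable beamformer pipeline.

## Worked example

Simulate a button-press task session (two marker streams; a left
sensorimotor source with an evoked motor field peaking 50 ms before the
press and beta suppression/rebound; a medial-frontal theta burst on
error trials only), epoch it, and image the beta rebound with SAM:

```r
library(megbeamer)

scn <- preset_sart(seed = 3)
sim <- simulate_recording(scn)
print(sim$recording)

spec   <- epoch_spec(-2, 2, filter = filter_spec(1, 100),
                     reject_motion = NULL)
ep_def <- epoch_recording(sim$recording, "correctDef_4th", spec)
ep_err <- epoch_recording(sim$recording, "errorWH", spec)

model <- head_model(c(0, 0, 5), 7.5)
grid  <- source_grid(model = model)     # 4 mm grid inside the sphere

beta <- sam_image(ep_def, model, grid,
                  baseline = c(-0.7, -0.4), active = c(0.4, 0.7),
                  mode = "pseudoT", filter = filter_spec(15, 30),
                  weights_epochs = list(ep_err))   # common weights
find_peaks(beta, threshold = 0.5 * max(beta$values))
```

```
<meg_recording> 151 channels x 107015 samples @ 600 S/s (178.4 s)
  MEG channels: 151 (0 excluded); CHL: present
  markers: correctDef_4th (48), errorWH (24)
     value   x  y  z index
1 43.58008 -19 32 58 13938
```

The positive pseudo-T peak (beta power higher in 0.4–0.7 s than in the
pre-movement baseline — the post-movement beta rebound) lands exactly on
the planted sensorimotor source at head-frame (−19, 32, 58) mm. The
error-minus-default theta contrast localises the planted frontal theta
source the same way (`contrast_image(ep_err, ep_def, ...)` with a
4–8 Hz band), and `virtual_sensor()` + `morlet_tfr()` recover the
time-frequency structure at either peak. Thresholding a group of such
images uses `permutation_threshold(images, alpha = 0.05, roi = ...)`.

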