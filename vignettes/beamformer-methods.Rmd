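---
title: "Minimum-variance beamformer source analysis: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-variance beamformer source analysis: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`megbeamer` implements a complete analysis chain for MEG source imaging
with minimum-variance beamformers: epoching of continuous recordings with
automated trial and channel rejection, spherical conductor head models,
a closed-form dipole forward model, event-related (ERB) and synthetic
aperture magnetometry (SAM) source imaging, virtual-sensor time courses
with Morlet time-frequency analysis, and omnibus sign-flip permutation
thresholds for group images. A dipole simulator generates complete
recordings with planted ground truth, so every stage of the chain is
testable end to end without any external data.

This vignette documents the models and their assumptions, the tunable
parameters with their defaults and units, the numerical choices made
where the design was genuinely open, and what the simulation-based
validation does and does not establish about real data.

# Coordinate frames and units

All field values are tesla internally; geometry is in centimetres in the
*head frame*: origin at the midpoint of the two ear fiducial coils, +x
through the nasion, +y toward the left ear, +z up (the common axial
convention for whole-head systems). Image grids are specified in
millimetres for NIfTI export; the conversion layers are explicit at the
API boundaries (`cm` for sensors/sources, `mm` for grids, `nA m` for
dipole moments).

# Forward model

The conductor is a homogeneous sphere. The magnetic field of a current
dipole in a spherical conductor has a closed form in sphere-centred
coordinates; two of its properties matter for everything downstream and
are enforced by tests:

* a dipole oriented along the radial direction produces no external
  field (silent source), so each source has only two effective degrees
  of freedom, spanned by a tangential basis;
* volume currents contribute nothing to the radial field component, so
  the radial projection of the field equals that of the primary-current
  (Biot–Savart) term alone. The test suite uses an independent
  Biot–Savart oracle on this projection, which agrees to ~1e-15
  relative.

The tangential basis at a source point is built deterministically: the
first coordinate axis (in x, y, z order) not parallel to the radial
direction is projected onto the tangent plane and normalised, and the
second vector completes a right-handed triad. This gives a reproducible
orientation parameterisation, including on the coordinate axes.

Multi-sphere models assign each channel its own local sphere, fitted to
head-shape points weighted by a Gaussian of distance to that channel's
sensing coil (scale 5 cm, a tunable parameter). On a spherical head all
local spheres coincide with the global fit; on realistic (ellipsoidal)
heads the origins vary smoothly across neighbouring channels. The
weighting scheme is this package's own choice — reported spherical-model
toolchains do not print one — and the scale is exposed as a parameter.

# Epoching and rejection

Epochs are cut around marker latencies with a fixed window (default
−2..2 s). The rejection order is deterministic and logged per trial with
exactly one primary reason:

1. *boundary*: the window extends beyond the recording;
2. *peak-to-peak / flat*: any non-excluded MEG channel exceeds the
   amplitude threshold (typically 3 pT) or is exactly flat;
3. *reset*: a single-sample step exceeds the threshold (flux jumps);
4. *channel exclusion*: channels whose individual rejection fraction is
   strictly above 90% (default) are excluded and the amplitude scan is
   repeated without them;
5. *motion*: mean MEG sensor motion from continuous head localization
   (CHL) exceeds 0.5 cm (default).

All thresholds are compared strictly (`>`), so "exceeds" retains ties.
Sensor motion is computed per sample as the displacement of the sensor
coils relative to the head: the rigid transform between the reference
fiducials and the instantaneous CHL fiducials (solved exactly from the
three coil points) is applied to every physical coil position, and
displacement magnitudes are averaged over coils and samples. The mean
head position option averages the CHL fiducials over the retained
epochs only and re-expresses the sensor geometry in that frame (and is
recomputed after trial rejection).

# Filtering

Band-pass filtering is a 4th-order Butterworth applied forward and
backward (zero phase), over reflection-padded segments whose padding
covers several periods of the lowest corner so that start-up transients
decay outside the data. When cutting epochs with pre-filtering enabled,
the filter is applied to a segment 50% longer than the epoch, centred on
it, and the epoch is cut from the filtered segment; at recording
boundaries the segment is truncated with a warning.

The powerline notch is a zero-phase spectral band-stop: the segment is
reflection-padded, Fourier transformed, and bins within `notch_width`
(default 7 Hz, full width) of the mains frequency and each harmonic
below Nyquist are zeroed. A realizable IIR stop-band of this width
necessarily has transition shoulders that change the signal again on a
second pass; the spectral form is idempotent by construction (the mask
is binary), removes the line tones essentially completely, and leaves
tones 10 Hz away untouched. Its cost is mild time-domain ringing of the
order of the reciprocal bandwidth, which is acceptable for line-noise
removal.

# Covariance and beamformer weights

The channel covariance is the average over trials and samples of the
outer product of the (optionally band-passed) channel vector, over a
half-open window `[start, end)` on the sample grid so that window
lengths are exact. Diagonal regularization is expressed as an RMS field
value, default 10 fT: `C <- C + (10 fT)^2 I`. Rank-deficient covariances
without regularization produce an explicit conditioning error (condition
number above 1e12) advising more regularization — there is deliberately
no silent pseudo-inverse fallback.

At each source location with tangential lead-field columns
`L = [l1 l2]`, the scalar beamformer orientation minimises
`t' (L' C^-1 L) t` over unit vectors `t` — equivalently maximises the
unit-gain output power — solved as the closed-form 2×2 symmetric
eigenproblem (with a deterministic sign convention). The weights are

    w = C^-1 L t / (t' L' C^-1 L t),

giving unit gain `w' L t = 1`. A brute-force 1° orientation scan in the
test suite confirms the eigen solution attains the scan maximum.

*Common weights*: for condition contrasts, the covariance is pooled over
the trials of both conditions (trial-count weighted), so that contrast
images are not biased by differences in the weights.

# ERB, SAM, and contrasts

The **event-related beamformer (ERB)** projects the trial-averaged
(phase-locked) sensor data through each location's weights and
noise-normalises: the image value is `|w' b(t)| / sqrt(w' Sn w)` with
`Sn` the regularization diagonal — a rectified pseudo-Z. The latency
axis is a step grid (default −0.3..0.3 s in 5 ms steps, 121 frames).
Because the noise model entering the normalisation is the regularization
diagonal, pseudo-Z magnitudes depend on the chosen regularization;
thresholds in such units are comparable only within an analysis.

**SAM** images compare source power between a baseline and an active
window. Weights come from the covariance of the pooled baseline and
active samples only (the covariance window used for ERB/virtual sensors
does not apply). With `Pa = w' Ca w` and `Pb = w' Cb w` (each averaged
per sample, so unequal window lengths are compared per unit time, with a
warning):

* pseudo-T = `(Pa − Pb) / (2 w' Sn w)`;
* pseudo-F = `Pa / Pb`.

SAM images are signed (not rectified); swapping the windows negates the
pseudo-T image exactly and inverts pseudo-F. The pseudo-T denominator
uses twice the projected regularization noise; published SAM variants
differ in this constant, so it is recorded in the image metadata.

**Contrasts** (condition 1 minus condition 2) compute per-condition
pseudo-T images with identical, pooled-covariance weights and subtract.

The **volumetric source grid** defaults to x −75..75, y −112..75,
z −50..85 mm at a 4 mm step, masked to voxels strictly inside the
conductor sphere with a 0.4 cm margin (lead fields vanish toward the
sphere centre's radial direction and weights become ill-conditioned at
the surface). **Surface** grids place sources at mesh vertices; with the
normal constraint the orientation is the vertex normal projected onto
the sphere's tangent plane and renormalised, otherwise the optimal
orientation is computed exactly as for volumes.

# Virtual sensors and time-frequency analysis

A virtual sensor recomputes weights for its own filter band and
covariance window (the band may differ from the imaging band), projects
every trial, and noise-normalises (pseudo-Z). Polarity is arbitrary (the
orientation sign convention is lexicographic, not physiological);
`polarity_align` flips all trials when the average at a stated latency
is negative, and leaves exact zeros unchanged.

The TFR uses complex Morlet wavelets: a complex exponential under a
Gaussian with `sigma_t = cycles / (2 pi f)`, default 7 cycles and 1 Hz
bins, truncated at ±4 sigma and L2-normalised (the L1/L2 choice is a
documented convention; L2 makes white-noise power flat across
frequency). Modes:

* `power`: mean over trials of squared magnitude (total power);
* `average`: squared magnitude of the transformed trial average
  (evoked, phase-locked power);
* `power_minus_average`: their difference (induced power).

Edge samples where the wavelet support extends beyond the epoch are
flagged in a validity mask rather than silently zero-padded, and a
warning marks requested frequencies below the resolvable floor for the
epoch length. Baseline correction subtracts the per-frequency mean over
a stated window and is idempotent.

# Group statistics

Subject images on a common grid are averaged voxelwise. Peaks are local
maxima above threshold (26-neighbourhood for volumetric grids), pruned
greedily so no two reported peaks are closer than a minimum separation,
ordered by value with lexicographic tie-breaks. Group peaks can be
refined per subject to the largest local maximum within a 10 mm ball,
falling back to the group location when the ball contains none.

The **omnibus permutation threshold** applies to signed images (SAM,
contrasts). The statistic is the maximum over ROI voxels of the absolute
group mean; its null distribution is built by flipping the sign of each
subject's image. Because the statistic is even, half the `2^N` sign
patterns are redundant: the first subject's sign is fixed, giving
`2^(N-1)` distinct permutations — 2048 for 12 subjects — enumerated
fully up to a cap of 4096 and randomly subsampled above it. The
threshold is the empirical `(1 - alpha)` quantile (inverse-ECDF); the
identity permutation is always a member of the null, so p-values cannot
fall below `1/n_permutations`. The two-sided (absolute-mean) form makes
the threshold invariant under a global sign flip; positive and negative
excursions are displayed per the user's polarity selection. A validation
harness (`type1_check`) measures the familywise false-positive rate on
smoothed-noise null groups; at alpha 0.05 with 8 subjects it falls in
the binomial band around 0.05.

# The simulator and what validation shows

`simulate_recording` builds continuous recordings through the same
forward model the beamformer inverts — with these deliberate
idealisations. The sensor array is a procedurally generated helmet: 151
axial gradiometers (5 cm baseline) on a Fibonacci lattice over a
spherical cap, inner coils 9.2 cm from the sphere origin, orientations
radial. Real sensor layouts are proprietary; the procedural cap
reproduces the coverage and channel count of a whole-head axial system.
Sources are current dipoles inside a 7.5 cm sphere at (0, 0, 5) cm.
Waveforms:

* `evoked_transient` — Gaussian pulse, phase-locked to events (default
  20 nA m, 25 ms width, peaking 50 ms before the event for the
  button-press preset);
* `band_burst` — oscillation at a random in-band frequency with random
  phase per trial (induced), Hann envelope;
* `oscillation_modulation` — ongoing narrow-band oscillation whose
  envelope drops around each event and rebounds after it
  (suppression/rebound gains 0.4 / 2.2 in the preset), emulating
  sensorimotor beta desynchronisation and rebound.

Noise is white sensor noise (7 fT/√Hz default) plus brain noise from
random interior dipoles (20 dipoles at 5 nA m RMS by default) with
band-limited waveforms. CHL fiducial channels are emitted every sample;
head motion is injected by rigidly transforming the fiducial triple over
scheduled segments. Motion affects the CHL stream (hence motion metrics
and rejection) but not the simulated fields — field modulation by
within-recording motion is not emulated.

The task preset (`preset_sart`) emits two marker streams,
`correctDef_4th` (48 events) and `errorWH` (24 events), at a 2.4 s mean
inter-trial interval with ±0.2 s jitter: a scaled-down session (a few
minutes of recording) with the response-locked sensorimotor sources and
the error-specific medial-frontal theta burst described above. Planted
source positions lie on the default 4 mm image lattice so that
localization can be scored in whole voxel steps. Validation harnesses
run the full public pipeline. `localization_check` plants 20 random
dipoles (100 trials each) and scores the ERB peak and orientation
against truth (median error within one 4 mm step, orientation within
5°). Its source population is the cortical shell under the array —
eccentricity 3–5.5 cm from the sphere origin, within the helmet cap,
inside the image bounding box — with cases resampled until the achieved
trial-average SNR is at least 2: tangential lead fields vanish toward
the sphere centre and sources below the sensor rim are outside the
array's coverage, so voxel-level accuracy is claimed (and tested) only
where a helmet system can deliver it. `sart_recovery_check` verifies
that the beta-rebound SAM image
(active 0.4–0.7 s vs baseline −0.7..−0.4 s, common weights) and the
error-minus-default theta contrast (active −0.5..0.5 s, baseline
−1.5..−0.5 s) peak at the planted sources.

Passing these checks demonstrates internal consistency — the imaging
chain inverts its own forward model under realistic noise, trial counts
and SNR — and correctness of the statistics and bookkeeping. It does not
establish performance on real data, where head models are approximate,
sensors are imperfectly calibrated, sources are extended rather than
point-like, and artifacts are not Gaussian. The problem sizes used by
the test suite and the acceptance script (tens of trials per condition,
single-subject recordings of a few minutes, 4 mm grids of ~20k voxels)
were chosen as the smallest sizes at which the planted effects are
recovered with comfortable margins.

# Known limitations

* Spherical (and local-sphere) conductors only; no BEM/FEM.
* The ERB noise normalisation uses the regularization diagonal, so
  pseudo-Z units are analysis-relative.
* Vendor binary formats are out of scope; the package defines its own
  open dataset container (JSON header + raw float64 payloads) and
  text dialects for shape/sphere files.
* The permutation test assumes subject-level sign symmetry under the
  null; groups below 8 subjects trigger a warning, as the null then has
  fewer than 128 atoms.
* Sliding-window SAM and MNI template warping are not implemented.
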