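Package: megbeamer
Title: Minimum-Variance Beamformer Source Analysis of MEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable analysis chain for magnetoencephalography (MEG):
    epoching of continuous recordings with automated trial and channel
    rejection (amplitude, flux-jump, head-motion criteria), spherical
    conductor head models fitted to head-shape points, a closed-form
    current-dipole forward model, event-related (ERB) and synthetic
    aperture magnetometry (SAM) minimum-variance beamformer source
    imaging with common-weights condition contrasts, virtual-sensor
    source time courses with Morlet wavelet time-frequency analysis,
    and omnibus sign-flip permutation thresholds for group images.
    Includes a dipole simulator that generates complete synthetic
    recordings with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    RNifti,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
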