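Package: rdica
Title: Motion-Artifact Reduction in Redundant Multichannel ECG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces motion artifacts in ambulatory electrocardiogram (ECG)
    recordings acquired redundantly at chest and back sites together with
    triaxial inertial (IMU) channels. Implements the redundant-denoising
    independent component analysis (Rd-ICA) pipeline: blind source separation
    of the redundant leads plus movement channels, selection of the cardiac
    component by correlation against a reference beat train synthesized from
    resting ensemble-average features at the measured heart rate, and a final
    wavelet-shrinkage polish. Ships the classical baselines (Daubechies-8
    wavelet shrinkage with the RiskShrink minimax rule, and wavelet-ICA on a
    stationary decomposition of a single lead), an ensemble-average beat
    characterizer with an 8-feature waveform parameterization, a seeded
    ground-truthed contaminated-record simulator, and a full evaluation suite:
    signal-to-noise ratios, exact dynamic time warping, a cross-correlation
    index, per-feature difference percentages, and the weighted distortion
    assessment (WDA) index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
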