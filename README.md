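# rdica — motion-artifact reduction for redundant multichannel ECG

Ambulatory and wearable ECG recordings made while the wearer moves are
contaminated by motion artifacts (MA): nonstationary interference from
electrode and cable motion that overlaps the cardiac band and defeats simple
filtering. `rdica` implements a redundant-denoising ICA (Rd-ICA) pipeline for
this problem, aimed at researchers and engineers working on wearable
monitoring and ECG signal quality: the same Einthoven lead is acquired at two
body sites (chest and back), together with a triaxial IMU co-located with the
electrodes. The two leads share one cardiac source while their artifact
mixtures differ, which turns artifact removal into a blind source separation
problem.

## The method

Observations are modeled as a linear mixture `x = A s` of independent
sources. For one lead, the 5-channel set
`(chest ECG, back ECG, imu_x, imu_y, imu_z)` is separated by FastICA
(deflation, tanh negentropy contrast) into sources `Y = W x`. The cardiac
component is identified automatically: the heart rate is measured on the
contaminated lead, a reference beat train is synthesized at that rate from
the subject's resting ensemble-average features, and the source with the
highest |Pearson r| against the reference is kept. Back-projection through
the estimated mixing matrix returns it in the chest-lead amplitude frame
(resolving ICA's sign/scale ambiguity), and a final Daubechies-8 wavelet
shrinkage (RiskShrink minimax soft thresholding) polishes the result.

The resting beat is parameterized by 8 ensemble-average (EA-ECG) features —
`a_P, d_P, t_P-R, a_R, d_R, t_R-T, a_T, d_T` (amplitudes in mV, durations
and extremum-to-R intervals in s) — and re-synthesized as a sum of
raised-cosine segment lobes over one beat period `T = 60 / HR`.

The package also ships the two classical baselines it is compared against
(wavelet shrinkage on the single lead; wavelet-ICA on a stationary wavelet
decomposition of the single lead), a seeded ground-truthed simulator of
contaminated records, and the full evaluation suite: SNR_in/out/improvement,
exact dynamic time warping with warp path and a percent distance,
a cross-correlation index, per-feature difference percentages with the
similarity transform `s = (100 − %diff)/100`, and the weighted distortion
assessment index `WDA = Σ w_i s_i / √(Σ w_i²)` with its four canonical
weight presets.

## Worked example

```r
library(rdica)

rest  <- default_rest_features(60)              # resting 8-feature beat, 60 bpm
model <- template_from_features(rest, 60, fs = 250)
sim   <- simulate_record(model, contamination_spec(target_snr_in = -5, seed = 42), 60)

fit <- rdica_denoise(sim$record, lead = "DII", rest_features = rest, seed = 42)
summary(fit)
#> Method: rdica
#> Samples: 15000 at 250 Hz (60.0 s)
#> Removed component RMS: 0.2677 mV (input RMS 0.3003 mV)
#> Component selection: source 3 (|r| = 0.281)
#>   |r| per source: 0.006 0.013 0.281 0.006 0.010

rep <- evaluate_denoising(sim$record$data[, 1], fit$denoised, 250, rest,
                          clean = sim$truth$clean_ecg)
print(rep)
#> SNR_in -5.000 dB, SNR_out 9.982 dB, SNR_imp 14.982 dB (clean: ground-truth)
#> DTW percent distance (EA beat vs reference beat): 1.37%
#> Cross-correlation index: 48.217
#> ...
#> WDA: equal=1.889, p_amplitude=1.830, qrs_amplitude=1.866, t_amplitude=1.880
```

The record was simulated at −5 dB input SNR; the pipeline selected the third
separated source as cardiac and raised the SNR by ~15 dB against the known
clean source. The per-beat DTW distance to the resting reference beat and
the WDA index (maximum `8/√8 ≈ 2.83` under equal weights) quantify how well
the waveform morphology survived.

A command-line interface covers the same pipeline
(`simulate`, `rest-features`, `denoise`, `evaluate`); see `inst/exec/rdica`
and `?run_cli`. Records travel as a plain CSV dialect or minimal WFDB
(.hea/.dat) files.

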