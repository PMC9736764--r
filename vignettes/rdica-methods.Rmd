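---
title: "Redundant-lead ICA denoising of motion-contaminated ECG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redundant-lead ICA denoising of motion-contaminated ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdica)
```

This vignette is the package's own account of the science it implements: the
signal models, the separation pipeline, every tunable that matters, the
numerical choices made where the design was genuinely open, and what the
built-in simulator does and does not establish about real recordings.

## 1. The problem and the measurement model

Motion artifact (MA) is the dominant noise source in ambulatory ECG: electrode
and tissue motion produces nonstationary interference that overlaps the
cardiac band (roughly 0.05–40 Hz), so it cannot be removed by band filtering
alone. The approach implemented here acquires the *same* bipolar lead at two
sites — chest and back — plus a triaxial IMU co-located with the electrodes.
Observations are modeled as a noiseless linear mixture

$$x = A\,s,$$

where the sources $s$ are assumed mutually independent with at most one
near-Gaussian member, and the number of observations equals the number of
sources ($m = n$, enforced). The two ECG channels share the cardiac source
with unit coefficient while their artifact coefficients differ by site; the
IMU channels observe the motion that drives the artifact. Under these
assumptions ICA recovers $Y = Wx$ up to permutation, sign and scale.

## 2. The parametric beat and the reference signal

A beat is a sum of raised-cosine (single-term Fourier) lobes, one per segment
$j \in \{P,Q,R,S,T,U\}$:

$$S_0(t) = \sum_j a_j \, \tfrac12\bigl(1 - \cos 2\pi u_j\bigr) + c_j,
\qquad u_j = (t - t_j)/d_j \in [0,1),$$

with amplitude $a_j$ (mV), duration $d_j$ (s), onset $t_j$ (s) and baseline
offset $c_j$ (default 0; baseline variation is treated as an artifact source,
not part of the beat). The lobe is smooth, compactly supported, and peaks at
exactly $a_j$ at its center, which makes segments locally identifiable. The
exact basis family behind published parametric ECG models is not fixed by the
sources available to us; the raised cosine is our choice and is isolated
behind `synthesize_beat()`, so an alternative lobe family could be swapped
without touching the rest of the package.

Eight features parameterize a beat: `a_P, d_P, t_P_R, a_R, d_R, t_R_T, a_T,
d_T`. `template_from_features()` inverts the feature-extraction conventions:

* the R-lobe center sits at a fixed fraction 0.4 of the beat period
  $T = 60/\mathrm{HR}$;
* P and T lobe centers precede/follow it by the extremum-to-R intervals;
* measured durations are 5%-threshold widths; a raised cosine exceeds 5% of
  its peak over a fraction $1 - \arccos(0.9)/\pi \approx 0.856$ of its
  duration, and this constant converts widths to lobe durations;
* the QRS complex is expanded into Q, R, S lobes with fixed geometry
  (Q and S centers one R-lobe duration before/after R, half its duration,
  amplitudes $-0.1$ and $-0.2$ of $a_R$), under which the measured QRS extent
  is $55/24$ of the R-lobe duration — the constant that keeps the 8-feature
  parameterization invertible.

Continuous signals concatenate beats with RR intervals
$T + \mathcal N(0, \sigma_{RR})$ truncated at $\pm 0.2\,T$; segment onsets
stay fixed relative to each beat's start, so variability stretches the
diastolic baseline, as in sinus rhythm. Heart rate is defined as
$60/\overline{RR}$ throughout.

Default resting features (0.15 mV / 90 ms P; 1.0 mV R with a 90 ms QRS;
0.3 mV / 160 ms T; PR and RT extremum intervals 180 and 300 ms) are ordinary
textbook values for a healthy adult at 60 bpm.

## 3. Ensemble averaging and feature extraction

R peaks are detected by a Pan-Tompkins-style chain: 5–15 Hz band-pass,
five-point derivative, squaring, 150 ms integration, an adaptive threshold
anchored at half the median of the top candidate energies, a 0.25 s
refractory period, a search-back pass that rescues missed beats inside RR
gaps longer than 1.6 times the median at half threshold, and a cleanup that
drops the weaker of two detections closer than 0.7 median RR. Detections are
refined to the raw-signal extremum within ±50 ms, with automatic polarity
handling for inverted leads.

Beats are epoched on $[R - 0.4\,\mathrm{RR}_{med},\ R + 0.6\,\mathrm{RR}_{med})$
and averaged aligned at R; the per-sample SD quantifies beat-to-beat
dispersion. Feature extraction conventions (all named constants in the code):
baseline is the mean of the PR isoelectric window 0.10–0.05 s before R;
search windows are P: $[-0.30, -0.10]$ s, QRS: $[\pm 0.05]$ s, T:
$[0.15, 0.45]$ s from R, shrunk proportionally when RR < 0.6 s; durations are
the extent over which $|$beat $-$ baseline$|$ exceeds 5% of the segment's
peak deviation; a P or T extremum below twice the baseline-window SD is
declared absent (amplitude 0, duration `NA`). The 5%-of-peak rule is one
defensible delimitation among several (tangent method, fixed windows); it is
what the generator inverts, so generator and extractor are mutually
consistent by construction.

## 4. The denoisers

**Wavelet shrinkage (WS).** Mallat pyramid with the 16-tap Daubechies-8
filters, periodic boundary (the signal is reflected up to a multiple of
$2^{levels}$), default depth 5. Detail coefficients are soft-thresholded with
the RiskShrink minimax rule $\lambda = \sigma(0.3936 + 0.1829\log_2 N)$ for
$N > 32$, else 0, with the universal threshold $\sigma\sqrt{2\ln N}$ behind a
flag. The noise scale $\sigma$ is the MAD/0.6745 of the *finest* detail
level: at coarser levels the cardiac waveform itself dominates the MAD, and a
per-level estimate over-shrinks the P and T waves badly enough to violate the
near-identity behavior a denoiser must have on clean input (measured:
correlation 0.88 vs 0.999 on a noiseless train).

**Wavelet-ICA (WICA).** The single lead is decomposed by an undecimated
(stationary) transform so all coefficient sequences share the signal's
length — the property that lets them form a multichannel ICA input without
resampling. After separation, retention is automated (visual inspection is
the known weakness of this method): each source's *single-source
reconstruction* — zero every other source, back-project, inverse transform —
is correlated against the reference beat train, and sources with
$|r| \ge \max(0.5\,r_{max},\ 0.2)$ are kept. The correlation must be taken on
reconstructed contributions, not on coefficient-domain sources: the analysis
filters delay each band differently, so zero-lag correlation in the
coefficient domain is uninformative (the clean-input sanity case scores 0.59
there and 0.99 with contribution scoring).

**Rd-ICA.** For the lead under repair: (1) measure HR on the contaminated
chest lead; (2) synthesize the reference train from the resting features at
that HR (zero jitter), shifted so an R peak coincides with the first detected
R; (3) assemble `(chest, back, imu_x, imu_y, imu_z)`; (4) FastICA —
deflation, tanh contrast, tolerance $10^{-6}$, 1000-iteration cap, seeded
initial vectors, with three stabilizations: a stalled two-cycle is damped by
averaging successive directions; the final deflation direction is taken
directly as the orthogonal complement (it is determined); and if a later
component finds no negentropy structure after restarts, the residual
subspace is completed with an orthonormal basis, since near-Gaussian
leftovers (sensor noise) have a flat contrast with no preferred directions.
(5) select the source with maximal $|r|$ against the reference (ties to the
lowest index; zero-variance sources score 0); (6) back-project only that
source onto the chest row of the estimated mixing matrix, restoring the
chest amplitude frame and adding back the channel mean; (7) polish with WS.
If HR estimation fails the resting HR substitutes, with a warning. If chest
and back are numerically identical there is no independent artifact content
to separate (and the covariance is singular); the ICA stage is skipped and
the chest lead is polished directly.

Whether the final polish should share the WS baseline's settings is not
fixed by our sources; identical defaults are used. Likewise the channel set
is the five channels of the lead under repair, not both lead pairs.

## 5. Evaluation indexes

* **SNR**: $\mathrm{SNR} = 10\log_{10}(\sum x_c^2 / \sum (x - x_c)^2)$ dB
  against the clean signal $x_c$, before (in) and after (out) denoising;
  improvement is their difference, exactly. When no ground truth exists the
  mean beat tiled at the detected R positions serves as an "EA-proxy" clean
  signal, flagged as such in every report.
* **DTW**: exact dynamic programming on $D[x,y] = |S_1[x] - S_2[y]|$ with
  moves right/down/diagonal; the warp path is backtraced from $(m,n)$
  preferring the diagonal on ties. The undefined "distance percentage" is
  normalized here as $100\,C(m,n) / (\text{path length} \times
  \text{reference amplitude range})$ and stated in every report; published
  absolute percentages are therefore not comparable, only orderings. The
  evaluation report applies DTW per beat — reference template against each
  epoched beat, averaged — because a distance on the ensemble-average beat is
  insensitive (averaging itself cancels artifact), and full-record DTW is
  quadratic in memory.
* **Cross-correlation index**: both sequences z-scored (population SD), the
  sliding dot product maximized over lags up to ±20% of the reference length
  and divided by $\sqrt N$; self-comparison scores $\sqrt N$. The scale of
  published values for this index implies an amplitude convention that is
  not recoverable; our convention is stated and used consistently.
* **Feature differences / WDA**: per-feature
  $\%\Delta_i = 100|e_i - r_i|/|r_i|$ (resting zeros excluded and flagged),
  similarity $s_i = (100 - \%\Delta_i)/100$ clamped to $[0,1]$ — unclamped
  negatives would make the aggregate sign-ambiguous. The weighted distortion
  assessment is the normalized projection
  $\mathrm{WDA} = \sum w_i s_i / \sqrt{\sum w_i^2}$, monotone in every
  similarity, invariant to joint weight rescaling, maximal at $8/\sqrt 8$
  for equal weights. Four presets: equal; P-, QRS- or T-amplitude at 0.9
  with all others 0.5. This algebraic form reproduces the published
  equal-weight values for the two columns that are arithmetically consistent
  with their inputs; the emphasized-weight cases are not derivable from the
  published inputs under this (or an RSS) form, so the form is configurable
  and only the equal-weight case is asserted.

## 6. The simulator: what it emulates, and what it cannot show

`simulate_record()` generates the study conditions used throughout the tests:
250 Hz, 60-second epochs, resting (artifact-free) vs walking records, RR
jitter 0.01 s (mild sinus variability), gait 1.6 Hz (normal pace), baseline
wander 0.3 Hz, broadband Laplacian noise, optional powerline. Sources are
built to satisfy the separation assumptions: the cardiac train and the gait
artifact are strongly non-Gaussian, the wander sinusoid sub-Gaussian, and
only the optional powerline term is near-Gaussian-adjacent; the broadband
term is Laplacian precisely so that "at most one Gaussian" holds.

The IMU model is a rigid-body torso oscillation: one waveform per harmonic
projected on the axes, on top of the constant gravity reading along a random
orientation. Two consequences are deliberate. First, the acceleration
magnitude responds almost linearly to the oscillation (gravity dominates the
norm), so the electrode-motion artifact — a memoryless, mildly nonlinear
function ($m + 0.15m^2 + 0.05m^3$) of that magnitude plus independent noise —
lies largely within the linear span of the IMU channels, which is what makes
the 5-channel unmixing able to cancel it. Second, the gait fundamental's
loading follows the gravity direction (walking's dominant acceleration is the
vertical bounce), so this linearity does not degenerate for unlucky
orientations. Chest and back mix the artifact sources with clearly different
coefficient patterns (wander/gait 0.25/0.55 vs 0.70/0.15) — the redundancy
premise — and artifact power is rescaled so the chest channel hits the
requested input SNR exactly.

What passing tests on this generator establish: the pipeline's internal
consistency (round trips, oracle equivalences), its behavior under the stated
mixing model, and the relative ordering of the three methods under
calibrated contamination. What they cannot establish: performance on real
walking artifacts, whose statistical structure (electrode pops, impedance
steps, nonstationary gait, muscle noise) no published characterization
constrains; absolute index values on human data; and any claim about
pathological morphologies, which the beat model deliberately excludes.

## 7. Numerical choices and degenerate inputs

Seeds are explicit arguments everywhere; the caller's RNG state is never
touched. Sample indices are 1-based (R idiom); times are seconds, amplitudes
millivolts; beat windows are half-open. Whitening uses the symmetric
eigendecomposition with a rank check at $10^{-10}$ of the largest
eigenvalue; exactly duplicated channels are an error. DTW refuses matrices
beyond $4\times 10^6$ cells and directs the user to beat-level comparison;
its interior is filled along anti-diagonals (vectorized). Flat signals are
"no peaks" errors; a constant DTW reference is an error when the percent
distance is requested; zero-variance inputs to the correlation index return
0 with a warning rather than NaN. Wavelet depth is validated against both
$2^{levels}$ and the dilated filter support.

Problem sizes in the test suite (60-second records, ten seeds per condition,
heart rates 60/80, input SNRs 0/−5/−10 dB) are the package's chosen standard
battery: large enough that median orderings are stable across seeds, small
enough to iterate on.

## 8. Known limitations

* The raised-cosine basis is a stand-in for the (unpublished) parametric
  family behind the reference model; morphology nuances (asymmetric T waves,
  biphasic P) are out of reach.
* Component selection relies on a constant-HR reference; long records with
  substantial HR drift weaken the zero-lag correlation, though selection only
  needs the cardiac source to out-correlate artifact sources.
* WICA's automated retention replaces expert visual inspection with a
  threshold rule; its constants are configuration values, not truths.
* The simulator's artifact family is invented plumbing constrained by stated
  assumptions, not by measured artifact statistics.
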