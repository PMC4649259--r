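---
title: "Models and methods behind museeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind museeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

museeg implements the full analysis chain for mobile multichannel EEG
recorded while subjects freely view visual art: preprocessing, stimulus
complexity classes, band-limited features, unsupervised clustering, and
time-varying directed connectivity. Because no public art-viewing EEG
corpus accompanies this problem, the package ships a first-class
synthetic-data module whose sessions carry known ground truth; every
downstream stage is validated as a closed loop against that truth. This
vignette records the models, the parameters that matter, and the design
choices made where the methodology was genuinely open.

## The synthetic study

A session is a piecewise-stationary VAR(2) process over the 20-channel
retained montage. Each channel is a damped second-order oscillator: a
posterior alpha rhythm (10 Hz), frontal theta (6 Hz) and central mu
(8 Hz), with the pole radius controlling spectral sharpness. Directed
coupling is an off-diagonal lag-1 coefficient; VAR order 2 is the
smallest order that yields band-specific spectral peaks, and lag-1
coupling the simplest directed term the Kalman tracker must follow
through a step change at block boundaries.

Complexity classes modulate the generator the way visual load modulates
EEG: viewing suppresses the posterior alpha pole radius (0.97 baseline,
0.93 moderate, 0.88 complex), engages frontal dynamics (0.90 / 0.92 /
0.94) and raises posterior-to-anterior and right-to-left coupling gains
(0.01 / 0.06 / 0.12). The magnitudes are the package's own calibration:
the study this emulates reports no quantitative effect sizes, so gains
were chosen once so that (a) every regime is comfortably stable and (b)
the effects are detectable by the connectivity and clustering stages at
desk scale — they are a designed analogue, not a reproduction.

Two amplitude details matter. First, innovation standard deviations are
calibrated per regime against the stationary covariance (a discrete
Lyapunov recursion) so uncoupled channels sit at 12 µV output SD,
keeping clean EEG in a realistic span and artifact amplitudes (200 µV
blinks, 500 µV pops) meaningful; a coupled target whose input already
exceeds the target floors its own innovation at zero. Second, coupling
routes avoid driving any channel at its own resonance — resonance-matched
chains (e.g. a 6 Hz channel driving another 6 Hz channel) amplify
amplitude explosively even when formally stationary. Sources are
posterior (10 Hz), targets frontal/central (6/8 Hz).

A shared low-frequency common-mode component (AR(1), ~19 µV SD) is added
to all channels. It emulates the strong mutual correlation of
referential EEG — without it, correlation-based bad-channel detection
would reject everything — and adds no directed structure; the common
average reference removes it exactly.

What the generator does **not** emulate: volume conduction (instantaneous
spatial mixing), 1/f broadband background, non-stationary artifacts
beyond the four stereotyped types, and any demographic effect unless a
gain multiplier is configured explicitly. Passing tests therefore show
the pipeline recovers the designed effect structure; they do not certify
performance on museum recordings.

## Preprocessing

The chain is: 0.1 Hz zero-phase high-pass → correlation-based
bad-channel rejection → peripheral-channel removal → simplified artifact
subspace reconstruction (ASR) → common average reference →
segmentation.

*Filtering.* "Zero-phase 8th order" is interpreted as an 8th-order
Butterworth applied forward-backward (effective 16th-order magnitude).
At 0.1 Hz on 1000 Hz data a single transfer-function realization is
numerically unstable in double precision, so all designs are factored
into second-order sections; each biquad is initialized at its
steady-state response to the first sample, which removes second-scale
start-up transients exactly (a constant input maps to exactly zero).

*Bad channels.* The recording is cut into 2-s windows; a channel is
flagged in a window when at least 80% of its pairwise Pearson
correlations fall below the threshold, and rejected when at least 50% of
windows flag it. The threshold is user-defined by design; 0.4 is this
package's default, not a literature value. Zero-variance windows count
as correlation 0.

*ASR.* A from-scratch simplified reconstruction: PCA directions from the
lowest-variance contiguous 10-s run, per-component windowed-RMS
thresholds at mean + 3 SD of the calibration windows, 0.5-s Hann windows
at 50% overlap, supra-threshold components zeroed and the window
reconstructed from the retained subspace. Overlap-add with a full
orthonormal basis means untouched stretches pass through bit-near
unchanged, and an infinite threshold is the exact identity.
Bit-compatibility with other ASR implementations is not claimed.

*Segmentation.* Each annotated arrival starts a 5-s epoch split into
five 1-s segments. The baseline epoch is the lowest-variance 5-s window
of the baseline block, since nothing constrains which baseline seconds
should be used; low variance is the natural "artifact-light" choice.

## Image complexity classes

Luminance uses the standard luma weights (0.299, 0.587, 0.114); dark
pixels are those below intensity 64 of 255. Texture is a complex Gabor
bank (4 dyadic wavelengths 4–32 px × orientations 0°/45°/90°/135°,
σ = 0.56λ), with DC-corrected kernels and edge-replicated convolution so
constant fields respond exactly zero; per-filter response-magnitude mean
and variance give 32 values. Gradients are central differences (Sobel by
option). Composite features are per-block mean gray minus global mean
over a 4 × 4 grid — exactly invariant to additive brightness shifts.
Feature vectors are z-scored (a package decision; the source method
leaves standardization unstated) and clustered hierarchically with
average linkage on cosine distance; the 3-cut group containing the known
blank-wall image is labeled baseline, and of the remaining groups the
one with larger mean luminance SD is labeled complex.

## EEG features

Five bands: delta 1–4, theta 4–7.5, alpha 8–12, beta 15–25, gamma
30–50 Hz. Per channel and 1-s segment:

* **Time (24):** kurtosis, SD, max |amplitude| and Shannon entropy on the
  unfiltered segment and on each band-filtered version (4th-order
  Butterworth band-pass, forward–backward). Entropy uses a 32-bin
  amplitude histogram normalized to probabilities — the estimator is a
  package decision. Inside feature tables, band filtering runs once per
  5-s epoch and is then sliced into segments, avoiding 1-s filter edge
  transients. A constant segment reports entropy 0 and kurtosis 0 with a
  degeneracy flag.
* **Frequency (15):** multitaper PSD (DPSS tapers computed from the
  tridiagonal formulation; time-bandwidth 2, 3 tapers) on a 1–50 Hz
  integer grid; per band the in-band power integral, the SD across
  in-band PSD bins (across bins, not tapers — a decision), and the
  Shannon entropy of the normalized in-band PSD.
* **Wavelet (15):** complex Morlet scalogram on the same grid, cycles
  growing with frequency (1.5 at 1 Hz up to 7) so low rows fit a 1-s
  segment while every band keeps at least 3 rows; the same three
  statistics on squared magnitudes.

Each 1-s segment is one observation; the five segments of an epoch are
not aggregated (the aggregation used originally is unstated).

## Feature selection and unsupervised clustering

mRMR discretizes each feature into 3 levels at mean ± SD and greedily
maximizes mutual information with the class labels minus mean mutual
information with already-selected features (difference criterion); the
top 50 features are kept.

US-ELM maps z-scored inputs through a random sigmoid hidden layer
(default 200 units, capped at n − 1 so the hidden-space eigenproblem
stays well conditioned) with orthonormalized input weights, then solves
the graph-Laplacian-regularized generalized eigenproblem
(I + λ HᵀLH) v = γ HᵀH v, keeping the 2nd…(nλ+1)th smallest
eigenvectors normalized to unit ‖Hv‖. The affinity graph is a
union-symmetrized kNN graph (k = 7) with heat-kernel weights at the
median pairwise distance; λ defaults to 1. Embeddings are clustered by a
full-covariance Gaussian mixture (mclust) or k-means with restarts.
Because the hidden layer is random, the search repeats embedding +
clustering (100 iterations by default) and reports accuracy
distributions per parameter configuration.

Accuracy is the plain (unadjusted) Rand index — pair agreements over all
pairs — matching the described pair-agreement scoring; the adjusted
version sits behind a flag. Because a random partition's plain Rand
against 3 balanced classes is well above 1/3, the package also reports
per-observation agreement (best one-to-one label matching), whose chance
level is exactly 1/number-of-classes; the Monte-Carlo chance check uses
direct agreement of uniform random assignments (mean exactly 1/3) rather
than best-permutation matching, which would be biased upward.

## Time-varying directed connectivity

The MVAAR model X(t) = Σₖ Λ(k,t) X(t−k) + E(t) is tracked by a Kalman
filter over the vectorized coefficients under a random-walk state model.
Three numerical choices matter:

* Channels are standardized inside the fit (coefficients rescaled back
  on output: Λᵢⱼ scales by sᵢ/sⱼ), so the shared scalar innovation
  variance weighs every channel equally even when coupling inflates some
  amplitudes.
* All target channels share the regressor z_t and therefore one state
  covariance recursion — an n² p-dimensional joint filter collapses to n
  coupled updates sharing a single (np × np) covariance, which is what
  makes 20-channel fits tractable in plain R.
* The state covariance starts diffuse (100 I), so early steps behave
  like recursive least squares; the update coefficient (default 1e-3)
  sets the tracking/variance trade-off afterwards. Model order defaults
  to 5 for real use; validation fits use the generator's true order.

Time-averaged coefficients discard the first 20% of samples as filter
burn-in. On stationary 3-channel VAR(2) data (5 s at 250 Hz) the
averaged coefficients agree with ordinary least squares and with ground
truth within RMSE 0.05, and a step coupling is crossed within ~60 ms.

The ADTF evaluates Λ(f,t) = I − Σₖ Λ(k,t) e^(−i2πfΔtk), inverts it to
H(f,t), and normalizes γ²(i,j,f,t) = |Hᵢⱼ|²/Σₘ|Hᵢₘ|², so each target row
sums to one over sources at every frequency and time (checked to 1e-6 on
every emitted tensor). The grid is 1–50 Hz at 1 Hz, evaluated every
10 ms by default. Near-singular Λ(f) is ridge-regularized with a
warning.

Patterns follow extended 10-20 rows: anterior = F/FC, posterior =
CP/P/PO/O (the central C row belongs to neither), left/right by odd/even
suffix with midline excluded from lateral patterns; the exact regional
membership is a package decision since none is published. Pattern
samples concatenate per-bin, per-time γ² above 0.3 (per-bin rather than
band-averaged — the per-bin reading matches the sample sizes implied by
coefficient-distribution histograms).

*Statistics.* Viewing/baseline and group contrasts use the rank-sum
(Mann–Whitney) test — samples are unpaired vectors of unequal size.
Raw concatenated γ² values are strongly autocorrelated within an epoch,
which makes a rank-sum test on them anti-conservative; the package
therefore calibrates the contrast with exchangeable units: independent
epochs each contribute one observation (their mean in-band pattern
coefficient) via `condition_contrast_replicate()`. Under the null this
holds the empirical type-I rate at the nominal 5% (4–5% over 200
replicates), and a right-to-left gain boost of 0.3 is detected at
p < 0.05 in every replicate. The concatenated-threshold route remains
the reported descriptive output (histograms, medians, counts).

## Problem sizes and orchestration

The bundled study profiles are `tiny` (4 subjects × 3 pieces, 250 Hz,
12-s baseline — the test-suite scale) and `default` (20 subjects × 8
pieces, 1000 Hz, 60-s baseline — the cohort analogue used by the
end-to-end benchmark, about 900 segment observations). The end-to-end
clustering analogue (`clustering_benchmark()`) achieves mean plain Rand
accuracy well above the 0.55 reference on the default profile; that
number certifies the designed separability of the synthetic classes
plus the correctness of the chain, nothing more.

`run_study()` executes the full flow under one validated configuration
(`study_config()`), whose defaults carry the stated analysis
conventions: 0.1 Hz/8th-order high-pass, 2-s bad-channel windows, 0.5-s
/ 3-SD ASR, 5-s epochs in 1-s segments, 50 mRMR features, 3 classes,
100 search iterations, 0.3 connectivity threshold. Configurations
round-trip losslessly through YAML; `make_fixture()` writes
BrainVision-style ASCII triplets plus ground-truth JSON sidecars.

## Known limitations

* The generator's effect sizes are designed, so accuracy figures are not
  comparable to field recordings.
* ASR is a simplified reconstruction, not a port of the published
  plug-in.
* JPEG stimulus input is not supported (PNG/TIFF are).
* Kalman innovation variance is shared across channels; channels with
  wildly heteroscedastic noise would need per-channel filters.
* Source-space connectivity and cross-frequency coupling are out of
  scope.
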