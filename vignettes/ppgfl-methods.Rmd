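---
title: "Methods: synthetic federated glucose monitoring from PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic federated glucose monitoring from PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the package's scope

Photoplethysmography (PPG) measures blood-volume pulsations optically; the
waveform carries one systolic peak (and usually a dicrotic component) per
heartbeat, and its morphology is modulated by physiological state, including
blood glucose. `ppgfl` implements, at desk scale and on fully synthetic data,
the complete processing chain of a non-invasive glucose monitor trained
across multiple sites without raw-data sharing:

1. synthetic PPG generation with a *known, planted* glucose-to-morphology
   effect (`generate_record()`, `generate_federated_datasets()`);
2. continuous wavelet transform (CWT) denoising with Donoho universal soft
   thresholding and baseline elimination (`denoise()`);
3. adaptive cycle-based segmentation into per-beat, length- and
   amplitude-normalized cycles (`segment_ppg()`);
4. a fixed 13-feature set (time-domain, spectral, nonlinear) per record
   (`extract_features()`);
5. binary particle swarm optimization (BPSO) for feature-subset selection
   (`run_bpso()`);
6. federated averaging (FedAvg) training of a shared multi-task network
   predicting continuous glucose (mg/dL) and the hypo/normo/hyper class
   (`fedglucose()`);
7. clinical evaluation: MAE/RMSE/MSE/MARD/R² and Clarke error grid analysis
   (`regression_metrics()`, `ceg_report()`).

Everything is driven by one global seed (`run_pipeline()`), so the whole
study is reproducible bit-for-bit. Because no clinical recordings ship with
the package, every quantitative claim here is about *recoverability of
planted structure*, not about real-patient accuracy.

## The synthetic generator

Each beat is the sum of two Gaussians: a systolic peak and a smaller,
delayed dicrotic bump. This is the simplest waveform that exposes every
morphological feature in the feature set (width, amplitude, slopes, area).
Defaults scale with the heart period so any rate in the supported 40-180 bpm
band produces separable, proportioned beats: systolic SD = 15% of the
period, dicrotic delay = 37.5% (0.12 s and 0.30 s at 75 bpm). Noise is
additive: white Gaussian noise, a sinusoidal baseline drift (default
0.05 Hz), and optional motion-artifact bumps drawn from a Poisson process.

The glucose effect is linear and explicit (`glucose_effect()`): per mg/dL
deviation from a 150 mg/dL reference, the half-amplitude pulse width grows
by 4e-4 s, the systolic amplitude by 2e-3 a.u., and the inter-beat interval
shrinks by 5e-4 s. These slopes were chosen once so that, over the default
50-300 mg/dL uniform BGL range, morphology varies by a physiologically
plausible 10-30% and the effect is statistically recoverable from 10-second
records — which is the generator's entire purpose: it provides ground truth
(beat times, labels, affected features) that the pipeline must recover.
Glucose classes use the standard clinical 70/180 mg/dL cut-offs,
configurable.

Cross-site heterogeneity shifts each client's mean BGL by up to
±`heterogeneity`·25 mg/dL and scales its noise level; `heterogeneity = 0`
gives identically distributed sites. The BGL distribution itself is uniform
on 50-300 mg/dL — a deliberate stress choice covering all three classes, with
no claim of epidemiological fidelity.

`simulate_feature_matrix()` bypasses signal synthesis and plants informative
features directly for selection experiments. The informative columns are
*complementary* noisy views of the standardized BGL: their noise components
sum to zero across the informative set, so the full set recovers the signal
exactly while every proper subset retains residual noise. This makes the
planted set the unique jointly sufficient subset — with independent noisy
copies, an optimal selector provably drops redundant planted features under
any size penalty, and "recovery" would be ill-posed.

What the generator does *not* emulate: pulse-wave propagation physics, PPG
optics, sensor saturation, arrhythmias, or real covariate structure between
glucose and heart rate. Passing tests therefore demonstrate algorithmic
correctness and end-to-end recoverability, not clinical performance.

## Wavelet denoising

The CWT is computed as the inner product of the signal with translated,
dilated, conjugated mother wavelets, with 1/sqrt(scale) energy
normalization, via FFT convolution (kernels truncated at ±6 scale-SDs;
convolution plans are cached per signal shape, which makes batch denoising
of many same-length records cheap). Two families are provided: the real
Mexican hat (Ricker — the second derivative of a Gaussian, written here with
the admissible negative exponent) and the complex Morlet. The Mexican hat is
the default denoising family because soft thresholding is defined on real
values; for Morlet the modulus is shrunk and the phase preserved.

Design choices where the procedure is underdetermined:

- **Threshold**: Donoho's universal threshold T = sigma·sqrt(2·ln N) with the
  natural logarithm and a single global T (one N, the record length).
- **Noise scale**: sigma is estimated as median(|finest-scale
  coefficients|)/0.6745, the standard robust estimator; no estimator is
  otherwise prescribed.
- **Scale grid**: 32 log-spaced scales spanning 0.5-8 Hz pseudo-frequency
  (scale = family center frequency / frequency). This covers the cardiac
  fundamental across 40-180 bpm plus the harmonics that carry beat
  morphology.
- **Baseline elimination**: coefficients at pseudo-frequencies below 0.5 Hz
  are zeroed. With the default grid the band-limited reconstruction already
  excludes sub-0.5 Hz oscillations; the rule acts explicitly when users
  extend the grid downward. The DC level, unrepresentable in any band-pass
  reconstruction, is restored by re-adding the record mean.
- **Inversion**: the inverse transform is the discretized double integral
  over scale and shift with measure da/a², normalized by the admissibility
  constant, computed numerically per family from the wavelet's spectrum
  (for the analytic Morlet the real part is doubled). On band-limited
  signals and a 64-scale grid the round trip is accurate to well under 5%
  relative L2 error.
- **Edges**: signals are reflect-padded by the largest wavelet half-support
  before analysis so the cone of influence falls on padding.

## Adaptive cycle-based segmentation

The peak detector reconciles two readings of "R-peak": candidates are local
maxima of the first derivative (steepest upstroke) that exceed an adaptive
threshold — half the rolling 2-second upper quartile of the positive
derivative, which makes detection invariant to amplitude scaling — and each
candidate is then snapped to the following local signal maximum within
0.2 s, so reported peaks sit on the systolic summits. A refractory interval
of 60/`max_hr` seconds suppresses double fires. (Defining peak k's search
window by its neighbouring peaks would be circular, which is why the
detector works candidate-first with a refractory rule instead.)

Cycle boundaries are midpoints between consecutive peaks (rounded down, so
interior cycles tile the record exactly); the first start and last end use a
fixed window Tf, by default half the median inter-peak interval (0.5 s when
fewer than two peaks exist), clipped to the record. Each cycle is linearly
resampled to Lg = 100 samples (configurable) and min-max scaled to [0, 1]; a
constant segment yields zeros plus a warning rather than NaNs.

## Features

The 13 features, in frozen order (mask bits index this order): pulse width
(time between half-amplitude crossings, s), pulse amplitude (max−min of the
raw segment — the normalized trace has unit amplitude by construction),
inter-pulse interval (s), area under the normalized cycle (trapezoidal),
upstroke and downstroke slopes (extreme forward differences × fs, a.u./s);
HRV as SDNN of the IPI series (ms), total Welch band power in 0.5-8 Hz in
dB (Hann window, 50% overlap, 512-sample segments), dominant frequency
(Welch argmax in 0.5-3 Hz); Higuchi fractal dimension (k_max = 8), Shannon
entropy of a 16-bin amplitude histogram (bits), and Poincaré SD1/SD2 in ms
from the variance identities SD1² = var(ΔIPI)/2,
SD2² = 2·var(IPI) − var(ΔIPI)/2 (clamped at zero; these equal the
rotated-scatter definitions asymptotically, not on very short series).
Per-record values are means over cycles; records too short for a stable
spectrum (<10 s) or with too few beats yield NA and are dropped, with a
logged count, before selection and training.

## Feature selection (BPSO)

Standard binary PSO with sigmoid transfer: velocities follow the
inertia/cognitive/social rule (defaults 0.729 and 1.49/1.49, 30 particles,
50 iterations, patience 10), velocities are clamped to ±6 to keep the
sigmoid responsive, and bits are sampled with probability sigmoid(v).
Fitness is `alpha·score − beta·|mask|/d` with alpha = 1, beta = 0.1 (the
weights are otherwise unspecified; beta = 0.1 prices one feature at one
accuracy point on d = 10). The empty mask scores −Inf. Because the
evaluator is deterministic (fixed CV folds), fitness values are memoized per
mask.

The default evaluator is 5-fold cross-validation of a lightweight model on
the selected columns: a linear discriminant classifier of the glucose class
scored by accuracy (`mode = "acc"`, the default, matching the accuracy form
of the fitness), or a linear regression scored by `max(0, 1 − RMSE/sd(y))`
(`mode = "rmse"`, for workflows that care about the regression target
rather than the class). LDA was chosen over nearest-neighbour after
verifying that exhaustive subset search under a k-NN evaluator fails to
retain redundant informative features — the evaluator, not the swarm, decides
recoverability.

## Federated multi-task training

`fedglucose()` is the package's central estimator. Each client minimizes
`Lt = λ1·Lr + λ2·Lc` where Lr is the MSE of the regression head and Lc the
categorical cross-entropy of the 3-class head (probabilities clipped at
1e-12). The implemented loss is the plain weighted sum of the two
per-sample means — no squaring of the log term, no additional 1/N on top of
already-averaged losses — with λ1 = λ2 = 1 by default.

The shared model is a 2-hidden-layer, 64-unit ReLU MLP with dropout 0.3 on
feature vectors (`model_kind = "mlp"`), or a linear model
(`model_kind = "linear"`) used for closed-form checks. A recurrent variant
(an LSTM over sequences of per-cycle feature vectors) was considered and
dropped: it requires sequence-length and statefulness conventions with no
canonical choice on per-record feature vectors, and none of the package's
properties depend on recurrence; the MLP is the tested design. BGL targets
and
features are z-scored inside the model using size-weighted per-client
moments (aggregate statistics are the only thing exchanged, like the
parameters themselves) and predictions are de-standardized to mg/dL.

Each round broadcasts the global parameters, runs `local_epochs` (default 2)
of mini-batch optimization per client (batch 32, Adam, learning rate 0.001,
20 rounds by default; plain SGD available, matching the gradient-descent
update rule), and aggregates with size-weighted FedAvg. Only parameter
vectors (or deltas, `param_delta()`) cross the client boundary; the
aggregation interface accepts nothing else. Per-epoch RNG streams are
derived from (seed, client, global epoch), which makes a one-client
federation bit-identical to uninterrupted centralized training under SGD;
under Adam the client optimizer moments restart each round, which is the
standard FedAvg behaviour and breaks bit-equality across rounds by design.

## Evaluation

Clarke error grid zones follow the original 1987 piecewise boundaries: A
within 20% of reference (or both readings below 70 mg/dL); E for
treatment-reversing errors (ref ≤ 70 with pred > 180, ref ≥ 180 with
pred < 70); C for overcorrection (pred > ref + 110 on ref ∈ [70, 290], or
pred < 1.4·ref − 182 on ref ∈ [130, 180]); D for dangerous failure to detect
(ref ≥ 240 or ≤ 70 with pred in the 70-180 band); B otherwise. Points on a
boundary resolve to the less severe zone. MARD is reported in percent.
Predictions entering the error grid are clamped to 1-1000 mg/dL (the grid is
defined on positive readings; an untrained model can otherwise emit
non-physical values).

## Problem sizes and numerical choices

The default study is 5 clients × 100 records of 10 s at 100 Hz, a 30%
per-client held-out test split, full 30×50 PSO, and 20 federated rounds; the
repeated-seed robustness checks in the test suite run the same study with
the swarm scaled to 10 particles × 15 iterations, a size at which selection
quality is unchanged on 13 features while ten full studies remain quick on a
laptop. Sub-seeds for every stage are derived from the global seed and stay
within 32-bit integer range. Degenerate inputs are handled explicitly:
empty peak lists are errors for boundary construction but valid (empty)
detector output; constant cycles normalize to zeros with a warning;
zero-variance references make R² NA rather than infinite; the empty feature
mask is never selectable.

## Known limitations

- Synthetic beats are two-Gaussian caricatures; real PPG morphology (pulse
  transit effects, respiratory modulation, sensor artifacts) is richer.
- The planted glucose effect is linear and noiseless in its slopes; real
  glucose-morphology coupling is weak, nonlinear and confounded.
- The recurrent model variant is not implemented (see above).
- PSO evaluator and fitness weights are package choices; other defensible
  choices (wrapper classifiers, stronger size penalties) change the selected
  subsets.
- The federation is simulated in-process; there is no secure aggregation,
  differential privacy, or communication failure model.
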