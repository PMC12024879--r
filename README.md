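# ppgfl

Non-invasive blood glucose estimation from photoplethysmography (PPG), with
federated learning — a fully synthetic, desk-scale R implementation of the
complete monitoring chain.

## What problem this addresses, and for whom

Blood glucose can in principle be tracked without finger-prick sampling:
glucose levels modulate blood-volume pulsations, so the morphology of the
PPG waveform (one systolic peak plus a dicrotic component per heartbeat)
carries a weak glucose signal. Exploiting it requires a long pipeline —
denoising, beat segmentation, feature engineering, feature selection, model
training — and, because clinical PPG data sit in separate institutions under
privacy constraints, the training step is naturally *federated*: sites
exchange model parameters, never raw recordings.

`ppgfl` is for researchers and students of biomedical signal processing and
federated learning who want a tested, reproducible, self-contained testbed
for this chain. No clinical data are included or required: a synthetic PPG
generator plants a *known* glucose-to-morphology effect, so every stage can
be validated against ground truth.

## The pipeline

For a record `ip(t)`:

1. **CWT denoising.** Wavelet coefficients
   `W(a, b) = a^{-1/2} ∫ ip(t) ψ*((t−b)/a) dt` (Mexican-hat or Morlet
   `ψ`) are soft-thresholded at Donoho's universal level
   `T = σ √(2 ln N)` with `σ = median(|finest-scale W|)/0.6745`, baseline
   content below 0.5 Hz is removed, and the signal is rebuilt by the inverse
   transform (`denoise()`).
2. **Adaptive cycle-based segmentation.** Peaks are detected from
   derivative maxima with an adaptive, amplitude-invariant threshold; cycle
   boundaries are midpoints between consecutive peaks
   (`St_k = (Rp_{k−1}+Rp_k)/2`), with fixed windows `Tf` at the record ends;
   each cycle is resampled to `Lg = 100` samples and min–max normalized
   (`segment_ppg()`).
3. **Features.** Thirteen per-record features: pulse width, amplitude,
   inter-pulse interval, AUC, upstroke/downstroke slopes; SDNN, Welch band
   power (dB), dominant frequency; Higuchi fractal dimension, Shannon
   entropy, Poincaré SD1/SD2 (`extract_features()`).
4. **Binary PSO feature selection.** Particles carry masks `Sb ∈ {0,1}^d`;
   velocities follow the inertia/cognitive/social rule (30 particles,
   `wt = 0.729`, `co1 = co2 = 1.49`, 50 iterations), bits are sampled
   through a sigmoid transfer, and fitness is
   `α·acc(Sb) − β·|Sb|/d` with a cross-validated evaluator (`run_bpso()`).
5. **Federated multi-task training.** Each client minimizes
   `Lt = λ1·Lr + λ2·Lc` (MSE regression of BGL + categorical cross-entropy
   over hypo/normo/hyper) on its own data; the server aggregates parameter
   vectors by size-weighted FedAvg `Mp ← Σ (N_i/N)·Mp_i` for 20 rounds
   (batch 32, Adam, lr 0.001). `fedglucose()` returns a classed model with
   `print`, `summary`, `coef`, `predict`, `plot`, `residuals` methods.
6. **Evaluation.** MAE, RMSE, MSE, MARD (%), R², and Clarke error grid
   zones A–E with the original 1987 boundaries (`regression_metrics()`,
   `ceg_report()`).

`run_pipeline()` executes all stages under one global seed.

## Worked example

```r
library(ppgfl)

rec <- generate_record(bgl = 210, seed = 42)   # one synthetic record
rec
#> Synthetic PPG record S1: 13 beats, BGL 210.0 mg/dL (hyper)
#> PPG signal: 1000 samples @ 100 Hz (10.00 s), amplitude [-0.0908, 1.46]

seg <- segment_ppg(denoise(rec$signal))
length(seg$cycles)
#> [1] 13

round(extract_features(rec), 3)
#>      pulse_width  pulse_amplitude              ipi              auc
#>            0.300            1.071            0.776            0.328
#>   slope_upstroke slope_downstroke         hrv_sdnn           psd_db
#>           19.674           17.803           29.683           -9.848
#>    dominant_freq      fractal_dim          entropy              sd1
#>            1.367            1.439            3.775           36.519
#>              sd2
#>           20.700
```

The record is hyperglycemic, so its planted morphology is wider and taller
than the 150 mg/dL reference (pulse width 0.30 s, amplitude 1.07 a.u.) with
a shortened inter-pulse interval (0.776 s). A small three-site federated
study end to end:

```r
man <- run_pipeline(pipeline_config(
  synth = list(n_clients = 3, records_per_client = 30),
  pso = list(n_particles = 10, max_iter = 10, patience = 5),
  seed = 1))
man
#> Pipeline run (seed 1)
#>   simulate  in    90  out    90     0.05s
#>   features  in    90  out    90     9.82s
#>   split     in    90  out    90     0.00s
#>   select    in    13  out     4     0.69s
#>   fedtrain  in    63  out  4740     0.20s
#>   evaluate  in    27  out    27     0.00s
#> Test RMSE 33.36 mg/dL (baseline 70.48), MARD 17.05%, A+B 96.3%

man$result$ceg
#> Clarke error grid (n = 27):
#>   Zone A:  59.26 %
#>   Zone B:  37.04 %
#>   Zone C:   0.00 %
#>   Zone D:   3.70 %
#>   Zone E:   0.00 %
#>   Clinically acceptable (A+B): 96.30 %
```

Reading this: PSO kept 4 of 13 features; the federated model's held-out
RMSE (33.4 mg/dL) is far below the predict-the-mean baseline (70.5 mg/dL),
and 96.3% of predictions fall in the clinically acceptable A+B zones of the
error grid. Larger studies (the default is 5 clients × 100 records) do
substantially better; this 90-record example trades accuracy for speed.

A command-line front end over the same functions is installed at
`inst/cli/ppgfl.R` with subcommands `simulate`, `denoise`, `segment`,
`features`, `select`, `fedtrain`, `evaluate`, `pipeline`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ppgfl.R", package="ppgfl"))')" \
  evaluate --pairs pairs.csv --out report.json
```

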