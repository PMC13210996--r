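# radarpcg

Contactless phonocardiography from continuous-wave Doppler radar, in R.

A 24 GHz Doppler radar pointed at the chest measures a complex baseband
signal whose phase tracks chest displacement: ΔR[n] = (λ/4π)·ψ_u[n].
Buried in that displacement, under millimetre-scale respiration and heartbeat
motion, are the micrometre-scale vibrations of the closing heart valves —
the heart sounds S1 and S2 that a stethoscope records as a phonocardiogram
(PCG). `radarpcg` implements the full chain that turns raw radar I/Q samples
into a PCG-like waveform and a four-state cardiac-phase segmentation:

* **Simulator** — labelled synthetic radar recordings: respiration, a smooth
  heartbeat pulse, Gaussian-windowed S1/S2 tone bursts with respiratory
  amplitude modulation and inspiratory S2 splitting, slow body-movement
  drift, quadrature impairments (amplitude mismatch, phase imbalance, DC
  offsets) and additive noise. Every downstream stage is testable without
  any external data.
* **Pre-processing** — geometric ellipse fitting and affine I/Q
  compensation, differentiate-and-cross-multiply (DACM) phase unwrapping,
  displacement conversion, polyphase resampling to 500 Hz, zero-phase
  5th-order Butterworth band-pass to [15, 150] Hz, timestamp
  synchronization and per-recording normalization, plus the first-difference
  and homomorphic-envelope feature streams.
* **Model** — a multitask self-attention 1D U-Net (four-level residual
  encoder 24→48→96→192, one 192-wide/8-head transformer encoder layer at the
  bottleneck, skip-connected decoder with linear upsampling, refinement
  block, and three heads: tanh-bounded waveform, envelope, and 4-class
  logits). 2,016,768 trainable parameters (7.69 MiB float32). Forward and
  backward passes are implemented in R with RcppArmadillo kernels; no
  deep-learning framework is required.
* **Objective** — L = α·L_wav + β·L_seg + γ·L_env with
  L_wav = 0.5·L1 + 0.5·multi-resolution-STFT (FFT 32/128/512, hop 8/32/128),
  L_seg = 0.7·class-weighted cross-entropy + 0.3·soft Dice
  (weights ∝ sqrt(mean(n)/n_c), unit mean), L_env = MAE;
  defaults α/β/γ = 0.70/0.20/0.10; AdamW training with subject-wise splits.
* **Metrics** — log-spectral distance (dB), envelope Pearson correlation,
  per-class precision/recall/F1 with micro/macro aggregation, per-state
  duration statistics, and event-based S1/S2 detection scoring with a
  ±100 ms tolerance.

Intended users: researchers in radar vital-sign monitoring and biomedical
signal processing who want a self-contained, inspectable reference
implementation of this processing chain.

## Worked example

```r
library(radarpcg)

rec <- simulate_recording(
  physio_config(heart_rate = 72),
  radar_config(noise_std = 0.005),
  iq_impairments(AI = 1.1, AQ = 0.9, psi_e = 0.2, OI = 0.3, OQ = -0.1),
  duration = 30, seed = 7)
rec
#> <synthetic_recording> subject01 / resting (30.0 s @ 2000 Hz, seed 7)

pair <- preprocess_recording(rec)      # compensate, DACM, resample, filter
cor(pair$y_rad, pair$y_pcg)
#> [1] 0.7169171
```

The recovered radar heart-sound stream correlates 0.72 with the clean
reference at this noise level (0.999 at zero noise). The per-state
statistics of the emitted labels reproduce the configured phase durations:

```r
state_statistics(pair$labels, pair$fs)
#>      state mean_duration  sd_duration    share
#> 1       S1    0.12244444 0.0008432740 14.69333
#> 2  systole    0.18561111 0.0217771542 22.27333
#> 3       S2    0.09251429 0.0008868791 10.79333
#> 4 diastole    0.43533333 0.0216465108 52.24000

build_model(model_config())
#> <pcg_unet> 1 input channel(s), 24-48-96-192 encoder channels,
#>   transformer 192 / 8 heads / 768 ffn; 2,016,768 trainable parameters (7.69 MiB float32)
```

A complete experiment — simulate a small cohort, pre-process, train with
subject-wise splits, and evaluate the held-out subject against the radar
input baseline — is one call:

```r
cfg <- experiment_config(epochs = 5, learning_rate = 1e-3, hop = 250,
                         seed = 42)
res <- run_end_to_end(cfg, n_subjects = 8, duration = 90)
res$report$aggregate
```

On this desk-scale protocol the trained network reduces the log-spectral
distance to the reference from 66.3 dB (radar input) to 42.9 dB and raises
the four-state micro-F1 on the held-out subject to 0.96 (macro-F1 0.95),
in about 13 minutes on one CPU. `res$out_dir` contains the loss history,
per-window metrics, the evaluation report and the model checkpoint.

A command-line wrapper over the same functions is installed at
`inst/cli/radarpcg.R` (`simulate`, `preprocess`, `train`, `evaluate`,
`run-all`).

## Scientific background and scope

The methods vignette (`vignettes/radarpcg-methods.Rmd`) documents the signal
model, every pre-processing step and its numerical pitfalls (edge padding
around the band-pass and resampler matters when the signal of interest is
1000× smaller than its neighbours), the exact architecture and how its
parameter count pins down the remaining structural choices, the loss
definitions, the evaluation protocol, and the known limitations of the
synthetic data. The optional loader for a locally converted copy of a public
synchronized radar–PCG dataset is described in `?load_public_dataset`.
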