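# ppg2ecg

Reconstruct the lead-II electrocardiogram (ECG) waveform from a
photoplethysmogram (PPG) alone.

PPG sensors — the optical pulse sensors in smartwatches and fingertip
clips — are cheap and comfortable, but rhythm diagnosis is read from the
ECG, whose electrodes are neither. Both signals are driven by the same
cardiac cycle: every R peak launches a pressure pulse that reaches the
periphery one pulse-transit time later. `ppg2ecg` learns that mapping and
inverts it, turning a PPG stream into an ECG waveform, for researchers in
physiological signal processing who want a complete, reproducible,
CPU-scale reference pipeline: preprocessing, model, training, inference,
evaluation and a synthetic data generator with exact ground truth.

## The model

Reconstruction is per-time-step sequence regression. A fixed-length PPG
segment $P_s$ is mapped to the concurrent ECG segment $E_s$ by a stack of
bidirectional LSTM blocks. The plain stack composes blocks,

$$E_s = (\ell^{5} \circ \ell^{4} \circ \ell^{3} \circ \ell^{2} \circ \ell^{1})(P_s),$$

while the densely connected variant feeds block $j+1$ the elementwise sum
of all earlier block outputs,

$$x^{j} = \sum_{k=1}^{j} \ell^{k},$$

and a per-time-step affine head reads the full fusion $x^n$ — every
hierarchical feature level at once. Training minimises per-segment RMSE
(Adam, best-validation-epoch checkpointing, subject-level splits).
Supporting machinery:

* type-I (odd, symmetric, exactly linear-phase) FIR band-pass filtering,
  applied zero-phase;
* cardiac-phase alignment for training pairs: the ECG-to-PPG lag is the
  cross-correlation maximum between the QRS-band ECG and the PPG's first
  difference (the systolic upstroke);
* Pan-Tompkins R-peak detection, tolerance-free nearest-beat matching and
  beat-timing error (mean |Δt| in seconds), per-subject Pearson r and
  RMSE, Student-t 95% CIs across subjects, paired Wilcoxon signed-rank
  model comparisons (exact null to n = 25);
* a paired ECG/PPG simulator (sum-of-Gaussians beats, asymmetric systolic
  pulses, heart-rate variability, baseline wander, motion artifacts,
  premature beats) with exact R-peak ground truth, in `clean` / `icu` /
  `ambulatory` presets.

The recurrent core (batched BiLSTM forward and full backpropagation
through time) is compiled C++ (RcppArmadillo).

## Worked example

```r
library(ppg2ecg)

# 8 simulated subjects, train a small dense model against the single-block
# baseline and compare on held-out subjects (a few minutes on one CPU):
res <- run_pipeline(system.file("extdata", "demo-config.yaml",
                                package = "ppg2ecg"))

glance(res$metrics)      # cohort summary of the dense model
res$comparison           # paired Wilcoxon: dense vs single-BiLSTM
```

A full study at a more informative scale (20 subjects of 120 s, 14/3/3
subject split, 5-block dense model vs the single-BiLSTM baseline, 6 hidden
units per direction, 25 epochs) is what the acceptance script below runs.
One run of it (`--seed 1`) printed:

```
  alignment_lag_samples        30 (n = 7500)
  detector_recall_pct          100 (n = 68)
  detector_false_positives     0 (n = 68)
  ci_coverage_pct              94.6 (n = 1000)
  dense_mean_rmse              0.0602 (n = 3)
  dense_mean_r                 0.8748 (n = 3)
  dense_mean_bte_s             0.00439 (n = 3)
  single_mean_rmse             0.0660 (n = 3)
  single_mean_r                0.8465 (n = 3)
  single_mean_bte_s            0.00449 (n = 3)
  dense_dominates_single       1 (n = 3)
```

Reading: on three held-out subjects the dense model reconstructs the ECG
with mean correlation 0.87 against the latency-aligned reference and
places R peaks within ~4 ms of the reference beats, dominating the
single-BiLSTM baseline on all three metrics — the ordering the dense
connection scheme is meant to buy (at this width the architectures are
below task saturation; see the vignette). The component rows confirm the
pipeline's internals: alignment recovers the simulated 0.25 s transit
time (30-31 samples at 125 Hz), the beat detector finds every beat of a
clean record with no false positives, and the across-subject confidence
intervals have near-nominal coverage.

Reconstruction itself needs PPG only:

```r
rec <- simulate_record(sim_config(duration_s = 60, seed = 1))
ecg_hat <- reconstruct(res$model, rec$ppg)   # a bio_signal, PPG in, ECG out
```

## Package layout

| | |
|---|---|
| `R/simulate.R` | paired ECG/PPG cohort generator with ground truth |
| `R/preprocess.R` | FIR design/application, alignment, segmentation |
| `R/model.R`, `src/dcblstm.cpp` | densely connected BiLSTM, compiled core |
| `R/train.R` | subject splits, Adam training loop, checkpoints |
| `R/reconstruct.R` | PPG-only inference and segment stitching |
| `R/pan_tompkins.R`, `R/metrics.R`, `R/evaluate.R` | detection, metrics, cohort evaluation, model comparison |
| `R/pipeline.R`, `inst/scripts/ppg2ecg` | end-to-end pipeline and CLI wrapper |

The methods vignette
(`vignettes/ppg-to-ecg-reconstruction.Rmd`) documents the model, every
tunable parameter, the evaluation-frame decision, and what the simulator
does and does not emulate.
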