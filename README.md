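# ventseg

Breath segmentation and patient–ventilator asynchrony (PVA)
quantification for mechanical-ventilator waveforms.

Bedside ventilators emit continuous airway-pressure (cm H2O) and flow
(L/min) waveforms, here at 50 Hz. Almost everything downstream of those
waveforms — asynchrony detection, tidal-volume analytics, closed-loop
research — first requires segmenting them into breaths: finding every
**inspiratory onset** (the ventilator starts a breath) and **expiratory
onset** (it cycles to expiration). Simple rules (flow zero crossings,
threshold-plus-backtracking) break down exactly where it matters, on
noisy recordings enriched for asynchronous breaths.

`ventseg` is for researchers working with ventilator waveform data. It
provides:

- a **dual-head attention-gated 1-D U-Net** segmenter: 352-sample
  (7.04 s) two-channel input windows, z-scored per window, predicting
  onset probabilities over the central 176 samples (3.52 s); encoder
  with doubling feature depth, dilated-convolution bottleneck,
  attention-gated skip connections, and separate inspiratory/expiratory
  heads with terminal sigmoids. Layers, backpropagation and the AdamW
  training loop are implemented in the package itself (R + BLAS, with
  C++ im2col hot loops), so no deep-learning framework is needed;
- its training objective, an **uncertainty-weighted focal + dice loss**

  L_total = L_focal/(2σ₁²) + L_dice/(2σ₂²) + log σ₁ + log σ₂,

  with L_focal = −α(1−p_t)^γ log p_t (α = 0.25, γ = 2) against the
  ~1:125 class imbalance of single-sample onset targets, the soft-dice
  complement for temporal alignment, and the σs learned during training;
- the two published **rule-based baselines** (zero crossing; derivative
  backtracking) and the reference-standard expiratory candidate
  algorithm;
- the **evaluation protocol**: one-to-one event matching at the exact
  timepoint and within a ±0.1 s tolerance, precision/recall/F1, breath-
  type stratification, and the two-proportion sample-size helper;
- **PVA quantification**: per-breath Ti/Te and trapezoidal TVi/TVe from
  flow, the two printed double-trigger definitions and the stacked-
  breath definition, and chi-squared comparison of asynchrony
  frequencies across segmentation sources;
- **Grad-CAM** for 1-D signals over the shared trunk;
- a calibrated **synthetic waveform generator** with planted ground
  truth (double-trigger pairs, stacked breaths, artifacts, sensor noise,
  baseline wander), since the motivating clinical dataset is not
  publicly deposited.

## Worked example

```r
library(ventseg)

# simulate two synthetic patients with planted asynchrony
cohort <- synth_cohort(sim_config(n_patients = 2, breaths_per_patient = 80,
                                  asynchrony_fraction = 0.3, seed = 7))
rec <- cohort[[1]]
print(rec)
#> <vent_record> patient synth001: 9525 samples (190.5 s at 50 Hz), annotated
print(rec$annotation)
#> <onset_annotation> 80 inspiratory, 80 expiratory onsets
#>       artifact double_trigger         normal        stacked
#>              1              8             53             18

# rule-based segmentation, matched against ground truth within 0.1 s
pred <- derivative_backtrack_segment(rec)
m <- match_events(rec$annotation$insp_onsets, pred$insp_onsets, tolerance = 5)
print(m)
#> <event_match> tp=77 fp=9 fn=3 (tolerance 5 samples)
round(prf1(m), 3)
#> precision    recall        f1
#>     0.895     0.963     0.928

# per-breath features and asynchrony quantification from ground truth
pva_report(breath_table(rec))
#> <pva_report> reference: 79 breaths
#>   double trigger (timing def):  8 (10.1%)
#>   double trigger (volume def):  8 (10.1%)
#>   stacked:                      17 (21.5%)
```

The derivative-backtracking baseline already misses or mislocates onsets
around the planted double triggers (F1 0.93 at ±0.1 s on this record);
the trained U-Net reaches F1 ≥ 0.99 on held-out synthetic patients under
3 L/min flow noise (see the test suite and acceptance script). The PVA
report applies the printed definitions: a double trigger by timing is a
breath whose expiratory time is under half the cohort-mean inspiratory
time; by volume, Te ≤ 0.3 s with TVe/TVi < 0.25 (or < 0.5 with
TVe < 100 mL); a stacked breath has Te > 0.3 s with TVe/TVi < 0.9.

Training the segmenter end-to-end:

```r
cfg <- experiment_config(
  sim   = sim_config(n_patients = 13, breaths_per_patient = 170,
                     noise_sd_flow = 3, seed = 101),
  model = model_config(depth = 3, base_filters = 8, kernel_size = 5,
                       bottleneck_dilations = c(1, 2),
                       dropout_bottleneck = 0.15, dropout_head = 0.1),
  train = train_config(max_epochs = 30, seed = 202),
  seed  = 303)
report <- run_experiment(cfg, verbose = TRUE)   # ~5 min on one CPU
subset(report$metrics, tolerance_samples == 5, c(method, onset_type, f1))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ventseg.R` (subcommands: `simulate`, `segment`, `evaluate`,
`pva`, `run-experiment`).

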