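---
title: "Methods: breath segmentation and asynchrony quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath segmentation and asynchrony quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mechanically ventilated patients produce continuous airway-pressure
(cm H2O) and flow (L/min) waveforms, here sampled at 50 Hz. Quantifying
patient–ventilator asynchronies (PVAs) such as double triggering and
breath stacking requires segmenting these waveforms into breaths, i.e.
locating every *inspiratory onset* (the ventilator starts delivering gas)
and *expiratory onset* (the ventilator cycles to expiration). Rule-based
segmenters that key on flow sign changes or thresholds degrade badly on
noisy, asynchrony-enriched data — the very data where segmentation matters
most. `ventseg` implements a learned segmenter, the published rule-based
baselines it is compared against, the tolerance-window evaluation
protocol, and definition-based PVA quantification, all exercised
end-to-end on synthetic waveforms with planted ground truth.

## The segmentation model

The segmenter is a dual-head attention-gated 1-D U-Net. Input windows are
352 samples (7.04 s) of two channels, each z-scored *within the window*
(population standard deviation; a constant channel maps to zeros).
Predictions cover only the central 176 samples (3.52 s, about one average
breath) to minimize edge effects; consecutive output spans tile a record
without overlap, so stitching inference windows back into a full-length
probability trace is exact. Record edges are reflection-padded by 88
samples so the first and last output spans keep full input context — edge
behavior is a design choice of this package, since "central output span"
architectures leave it open.

The network: an encoder of `depth` levels (default 4), each
`convs_per_block` (2) 1-D convolutions (kernel 7) with LeakyReLU
(slope 0.01) followed by max-pooling stride 2, with feature depth
doubling from `base_filters` (32); a bottleneck of dilated convolutions
(rates 1, 2, 4) with dropout (0.3); a decoder of transposed-convolution
upsampling blocks whose skip connections are gated by additive attention
(skip and gating signal each pass a 1×1 convolution, are summed, ReLU,
projected to one channel, sigmoid; the coefficient multiplies the skip
before concatenation — the canonical attention-U-Net gate, chosen here
because "gated by attention" admits several readings); a center crop to
176 samples; and two task heads (inspiratory, expiratory), each a
convolution, layer normalization, dropout (0.2), a position-wise dense
layer with GELU, and a one-channel dense layer with terminal sigmoid.
Targets are one-hot at single onset samples: the model is trained on
exact onset time points, not smeared windows.

The layers, backpropagation and AdamW optimizer are implemented in this
package directly (R with BLAS matrix products; the im2col/col2im hot
loops in C++). Analytic gradients are pinned against finite differences
in the test suite.

### Loss

Training minimizes an uncertainty-weighted composite of focal and dice
terms,

$$\mathcal{L}_{total}
  = \frac{1}{2\sigma_1^2}\mathcal{L}_{focal}
  + \frac{1}{2\sigma_2^2}\mathcal{L}_{dice}
  + \log\sigma_1 + \log\sigma_2,$$

with $\mathcal{L}_{focal} = -\alpha(1-p_t)^\gamma \log p_t$ averaged over
elements ($\alpha = 0.25$, $\gamma = 2$; $p_t$ is the probability of the
true class) addressing the extreme class imbalance (one onset sample per
~125), and
$\mathcal{L}_{dice} = 1 - (2\sum_i p_i g_i + \epsilon)/(\sum_i p_i + \sum_i g_i + \epsilon)$
($\epsilon = 10^{-6}$) encouraging temporal alignment of predicted event
mass. The $\sigma$s are learned jointly with the weights, parameterized
as $\log\sigma^2$ (initialized 0) so positivity is automatic; the log
terms keep them from diverging, and minimizing over a $\sigma$ alone has
the closed-form stationary point $\sigma^2 = \mathcal{L}$.

The equation as printed attaches one $\sigma$ per *loss term* computed
over both heads jointly; the phrase "balance the contributions of the two
outputs" also admits one $\sigma$ per *head*. Both readings are
implemented (`loss_config(pairing = "by_loss")`, the default, vs
`"by_head"`).

Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before logarithms.
Optimization: AdamW, learning rate 5e-4, mini-batches of 32 windows,
decoupled weight decay 1e-2 on weight matrices only (the decay magnitude
is a package default; only its presence is prescribed), He
initialization, early stopping on validation loss with patience 10 and
minimum delta 1e-4, returning the weights of the best validation epoch.
All randomness (initialization, shuffling, dropout) flows from a single
seed, so training is bit-reproducible.

### Post-processing

Stitched probability traces are turned into events by taking strict
local maxima above 0.5 (strictly greater), merging candidates of the same
type closer than a debounce radius (default 5 samples = 0.1 s, matching
the evaluation tolerance; the value is exposed since none is prescribed),
and keeping at most one expiratory onset — the highest-probability one —
per inspiratory interval. Expiratory candidates in the open segments
before the first or after the last inspiratory event are kept only when
unique there; consequently an annotation may contain one expiratory onset
before the first inspiratory onset (a partial leading breath), which the
`onset_annotation` validator permits.

## Rule-based baselines

*Zero crossing*: inspiratory onsets where flow crosses from negative to
non-negative, expiratory onsets where it crosses from positive to
non-positive. The crossing is assigned to the first sample on the new
sign's side; exact zeros count with the non-negative side. Faithful to
the published rule, no debouncing or pairing constraint is applied — its
false-positive explosion under noise is the baseline's documented failure
mode.

*Derivative backtracking*: inspiratory onsets anchor on flow exceeding
12 L/min and step backward "to where the derivative began to change";
expiratory onsets anchor on flow below −5 L/min persisting for at least
25 ms after the inspiratory onset and step backward to a zero crossing or
plateau. The published source code is unavailable, so "began to change"
is operationalized as a sign change of the first difference
(`flow[i] − flow[i−1]`) or a drop of its magnitude to ≤ `derivative_eps`
(default 0.5 L/min per sample, exposed as a parameter); "plateaued" uses
the same tolerance; 25 ms at 50 Hz (1.25 samples) rounds up to 2 samples
since "at least" is a lower bound. Expiratory search runs per inspiratory
interval, as the published description reads.

*Reference expiratory candidates*: the algorithm used to seed the
reference standard — per breath interval, the first positive-to-
non-positive zero crossing after the maximal contiguous positive-flow
segment with the largest trapezoidal area.

## Evaluation protocol

Events are matched one-to-one at a tolerance of 0 samples (exact
timepoint) or ±5 samples (0.1 s at 50 Hz, inclusive), greedily in
increasing absolute offset with ties broken toward the earlier reference
event; precision, recall and F1 follow from the matched counts. The
matching rule of the original protocol is unstated; greedy-by-offset is
pinned here, and an exhaustive maximum-cardinality, minimum-total-offset
assignment mode exists as a test oracle. The two coincide whenever
reference events are separated by more than twice the tolerance — true
for breath onsets (≥ ~1 s apart) at a 0.1 s tolerance — because the
compatibility graph then decomposes into disjoint stars; the property
test generates instances in that regime, and a companion test documents
that greedy can only under-match on adversarially dense instances.

Stratified evaluation assigns each event to the stratum (normal / PVA /
artifact) of its enclosing reference breath; the generator's finer
double-trigger and stacked labels fold into the PVA stratum.

The sample-size helper reproduces the protocol's power statement:
detecting an improvement from 70% to 80% accurately segmented breaths at
80% power and two-sided α = 0.05 requires
$\lceil (z_{1-\alpha/2}+z_{power})^2\,(p_0 q_0 + p_1 q_1)/(p_1-p_0)^2 \rceil
= 291$ breaths with the unpooled two-sample normal approximation (the
pooled Fleiss variant, 294, sits behind a flag).

## PVA quantification

A breath is the interval between consecutive inspiratory onsets. Per
breath: Ti and Te from onsets; TVi as the trapezoidal integral of
positive flow over the inspiratory phase and TVe of negative-flow
magnitude over the expiratory phase (L/min × 1000/60 → mL/s). Breaths
lacking an expiratory onset or a successor are dropped and counted.
Three printed definitions are applied: double triggering by timing
(Te < 0.5 × mean Ti, strict; the mean is pooled over the analyzed cohort
— per-patient scoping is available via an argument, since the original
scope is unstated), double triggering by volume (Te ≤ 0.3 s and
TVe/TVi < 0.25, or TVe/TVi < 0.5 with TVe < 100 mL), and stacking
(Te > 0.3 s, strict, with TVe/TVi < 0.9). Frequencies from different
segmentation sources are compared per category by Pearson chi-squared on
the 2×2 flagged-by-source table, without continuity correction (only
"chi-squared tests" is prescribed); Welch t-tests cover continuous
comparisons.

## Grad-CAM

For interpretability, the gradient of a head's pre-sigmoid logit at a
chosen output timestep (logit rather than probability, the standard
choice where unstated) is taken with respect to the last shared-trunk
convolution — the final decoder convolution before the center crop, which
in this architecture already sits at full input resolution, so no
upsampling of the heat is needed. Per-channel weights are time-averaged
gradients; the heat is the rectified weighted sum of feature maps,
max-normalized. Zero gradients yield flat zero heat with a warning.

## The synthetic generator

Real bedside recordings of this kind are not publicly deposited, so
validation runs on synthetic cohorts with planted ground truth,
calibrated to the summary statistics of an adult volume-targeted
ventilation cohort enriched for asynchrony: Ti uniform on 0.8–0.9 s,
normal Te on 1.1–2.8 s, decelerating (80%) or square (20%) inspiratory
flow with peaks of 45–70 and 25–36 L/min respectively (tidal volumes
~300–500 mL), PEEP 5–8 and peak pressures 21–34 cm H2O, ~30% of breaths
asynchronous and ~5% artifact-laden. Expiration is a single exponential
decay (time constant Te/3) rescaled so the exhaled volume equals
`exhale_fraction` × TVi under the same trapezoidal convention the breath
table uses, making planted TVe/TVi exactly recoverable from ground-truth
onsets. Double-trigger insufflations plant Te on 0.10–0.25 s with
TVe/TVi on 0.05–0.20; stacked breaths Te on 0.5–1.2 s with TVe/TVi on
0.5–0.85; normal breaths exhale ≥ 96%. All planted values keep at least
0.05 margin from every classification boundary. Records begin
mid-exhalation so the first inspiratory onset is a genuine flow crossing.
Gaussian sensor noise (defaults: 1 L/min flow, 0.5 cm H2O pressure),
slow sinusoidal baseline wander (0.05–0.15 Hz, amplitude 0.3 per
channel — the residual drift of an auto-zeroed sensor; larger drift
would bias multi-second volume integrals by tens of mL and make the
volume-ratio definitions unusable, on synthetic and real data alike) and
cough-like damped
10 Hz bursts on artifact breaths are added only after the exact onset
indices are recorded.

What the generator does *not* emulate: lung-mechanics dynamics
(resistance/compliance), patient effort signals, mode changes, circuit
condensation, or the long-tailed artifact menagerie of real ICU data.
Passing tests therefore demonstrate correct implementation and parameter
recovery under controlled conditions, not clinical performance.

## Validation scale and expected behavior

The package's end-to-end validation trains a reduced network — depth 3,
8 base filters, kernel 5, dilations (1, 2), dropout 0.15/0.1 — on a
13-patient synthetic cohort (~2,200 breaths, ~1,150 training windows)
with flow noise of 3 L/min, for at most 30 epochs; these sizes are the
package's chosen desk-scale validation conditions. On the held-out
patients the trained model reaches F1 ≥ 0.95 for both onset types within
±0.1 s and exceeds the derivative-backtracking baseline, reproducing the
direction (not the magnitudes) of the published comparison; asynchrony
frequencies computed from model onsets match ground-truth-derived
frequencies with non-significant chi-squared differences. Full-scale
defaults (depth 4, 32 filters, 33 patients × 294 breaths) are exposed in
the configuration objects.

Known limitations: derivative backtracking, faithfully implemented,
mislocates inspiratory onsets that follow a truncated expiration (the
backward walk traverses the short, steep expiratory limb), so its
recovery is only perfect on normal-breath records — consistent with the
published stratified results, and the reason the 100%-recovery check runs
on asynchrony-free cohorts. Training on one CPU in R is practical at the
validation scale but slow at full scale; the architecture code is
framework-free by design, and no attempt is made to reproduce the
published parameter counts, which are not fully specified.
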