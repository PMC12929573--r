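---
title: "Methods: ApEn topographies and classifier benchmarking for disorders of consciousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ApEn topographies and classifier benchmarking for disorders of consciousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

Distinguishing the vegetative state / unresponsive wakefulness syndrome
(VS/UWS) from the minimally conscious state (MCS) is one of the hardest and
most consequential judgments in neurorehabilitation: behavioral scales
(CRS-R) are the reference standard but are confounded by motor impairment
and fluctuating arousal. EEG signal complexity offers an objective
correlate of residual cortical function. This package implements a complete
diagnostic pipeline around one complexity statistic — approximate entropy
(ApEn) — computed channel-wise from 16-channel, 500 Hz EEG recorded in two
conditions per patient (eyes-closed rest, and stimulation with the
patient's preferred music):

1. **Signal preparation**: 0.3 Hz high-pass, 70 Hz low-pass, 50 Hz notch
   (all zero-phase), selection of a 32,768-sample (65.536 s) analysis
   segment after discarding an initial noisy portion, and segmentation into
   60 non-overlapping epochs per condition.
2. **ApEn extraction**: classical Pincus ApEn with m = 2 and
   r = 0.2 × SD, one value per channel per epoch.
3. **Topographic imaging**: each epoch's 16 values are interpolated over
   the unit head disk, 20 topographies are tiled into a 512×512 RGB image,
   center-cropped to 256×256 — three images per condition, six per patient
   (120 topographies).
4. **Classification**: a four-block CNN on the images; a linear SVM and a
   GRNN on ANOVA-screened electrode–condition mean-ApEn features.
5. **Evaluation**: confusion-matrix rates with exact binomial CIs, ROC/AUC,
   and DeLong tests between the correlated AUCs.

Because no clinical recordings are distributed, the package ships a
calibrated synthetic-cohort generator that reproduces the *statistical
structure* the analysis relies on; every stage is tested against it.

# Approximate entropy

For a series $x_1,\dots,x_L$, templates
$u_i^{(k)} = (x_i,\dots,x_{i+k-1})$, and Chebyshev distance $d$, define

$$C_i^k(r) = \frac{\#\{j : d(u_i^{(k)}, u_j^{(k)}) \le r\}}{L-k+1},
\qquad
\Phi^k(r) = \frac{1}{L-k+1} \sum_i \log C_i^k(r),$$

$$\mathrm{ApEn}(m, r, L) = \Phi^m(r) - \Phi^{m+1}(r).$$

Numerical conventions, each fixed deliberately:

* **Self-matches included** in the counts — the classical estimator. This
  guarantees $C_i^k > 0$ (the logarithm is always defined) and
  non-negativity of the estimate.
* **Tolerance** $r = 0.2 \times$ *population* SD (divide by $n$), fixed by
  oracle recomputation in the tests. Tolerance is recomputed per window —
  whether the original analysis used per-window or per-recording SD is not
  determinable, so it is the configurable default.
* **Degenerate input**: a constant series has $r = 0$; the implementation
  returns 0 directly, the value required for perfectly regular sequences.
* **Distance** is the Chebyshev max-norm, the standard ApEn choice.

The compiled kernel counts template pairs symmetrically and derives the
$(m{+}1)$-length matches from the $m$-length matches in one pass; the
integer counts, and therefore the result, are identical to a literal
double-loop implementation — the suite asserts equality to $10^{-12}$
against an independent oracle on 200 random series and exercises m ∈
{1, 2, 3}.

# The synthetic cohort

Channels are MIX-family processes: a 10 Hz sinusoid whose samples are
independently replaced by i.i.d. uniform noise with probability $p$. The
MIX family is the canonical ApEn test process because its expected ApEn is
monotone in $p$, which makes complexity *calibratable*: the generator
simulates the $p \mapsto$ ApEn curve, monotonizes it, and inverts it by
interpolation. Calibration is performed on series passed through the same
band-pass filters the pipeline applies (on padded series, cropped to the
epoch length), because low-pass filtering materially lowers the ApEn of
the noise component — calibrating on raw MIX series would bias every
channel high.

Per-channel targets are the published group-level mean-ApEn summary bundled
in `reference_group_apen.csv`: VS/UWS means around 0.60–0.73, MCS means
0.65–0.82, with the MCS elevation concentrated on left-hemisphere channels
and enhanced under music. On top of the group targets each patient draws

* a patient-level offset $\delta \sim N(0, 0.06)$ shared across channels
  and conditions, and
* independent channel jitter $\sim N(0, 0.04)$.

The published per-electrode SDs (±0.14–0.24) describe between-patient
clinical heterogeneity — etiology, lesion location — that the generator
explicitly does not model (its Non-goals). The defaults above represent
measurement-level variability only; they were chosen once, on the grounds
that the generator's purpose is to make the *configured* effect sizes (the
published mean differences) recoverable at the 20+20 desk scale the test
suite runs. Consequently the synthetic screening selects more than the
published 15 features (higher power at equal mean differences); the
15-feature count is reproduced exactly from the published table itself,
which is the only place it is determinate.

CRS-R totals follow the spec'd coupling:
`total = 9 + round(z + N(0, 2))` for MCS (clipped to 6–14), where `z` is
the standardized patient offset, yielding Spearman ρ ≈ 0.43 between mean
ApEn and CRS-R total in MCS and ρ ≈ 0 in VS/UWS (totals
`4 + round(N(0, 1.5))`, clipped 0–8, uncoupled). Signals are scaled to
30 µV SD, get a 5 µV 50 Hz mains component (removed by the notch, so the
filters do real work), and are serializable to EDF (16-bit, ±500 µV
physical range — quantization ≈ 0.015 µV, negligible against the signal).
An optional EMG-burst flag overwrites one epoch with high-amplitude
broadband noise to exercise the artifact screen.

**What passing tests do and do not show**: the generator produces
stationary, narrow-band-plus-noise signals with exact class structure. It
has no 1/f spectrum, no ERPs, sleep spindles, eye blinks or drifting
vigilance, and its within-patient epoch variance is a free parameter (the
original analysis never characterizes it). Recovery results on it
demonstrate the pipeline's correctness and sensitivity, not clinical
performance.

# Signal preparation choices

The band-pass is realized as an order-2 high-pass plus order-2 low-pass
cascade (4 poles total) with an order-2 band-stop notch (48–52 Hz), all
applied forward-backward. Zero-phase filtering matters here: phase
distortion would alter local predictability and hence the entropy itself.
The test suite verifies on pure tones: at least 20 dB attenuation at
50 Hz, 10 Hz passband gain within 5%, and DC suppressed below 1% of its
amplitude after the edge transient. The initial discard defaults to 2 s,
configurable.

The segmentation bookkeeping cannot be reconciled exactly from the source
material — a fixed N of 4,096, a 2 s sliding window, 1 s epochs, and 60
segments of a 65.536 s selection (~1.09 s each) cannot all hold at once.
The package therefore exposes `epoch_mode` with three settings
(`n60` default, `fixed1s`, `fixed2s`) and takes no position on which was
actually used; the default reproduces the arithmetic that cross-checks
(60 segments × 2 conditions → 120 topographies → 6 images per patient).

The entropy-inflation screen replaces manual artifact inspection: EMG
contamination raises ApEn across the entire montage, so epochs whose
montage-mean ApEn exceeds the recording mean by more than k·SD (k = 3)
are excluded; excluding more than half the epochs is treated as a
contaminated recording and raises. At k = 3 on clean data, 1–2 epochs per
recording occasionally fall above the threshold; the image builder then
repeats the last frame to fill the 20-per-image layout and records the
repetition in the image provenance.

# Topographic images

Electrode positions are a deterministic 2-D projection of the 10–20
layout with exact left–right mirror symmetry. Interpolation over the head
disk is a thin-plate spline — smooth and exact at the electrodes, the two
properties the rendering contract requires; inverse-distance weighting is
available as an option. (No scattered piecewise-cubic interpolator is
part of the package's dependency set; the TPS is the package's design
choice and the tests pin its node-exactness.) Because the interpolant is
linear in the 16 node values, the whole in-disk field is one precomputed
matrix–vector product per frame, making rendering cheap and bit-exactly
reproducible.

The color scale is fixed at ApEn ∈ [0, 1.2] with a fixed
perceptually-ordered map: per-image autoscaling would erase the class
signal that the CNN is supposed to find. Values outside the scale are
clipped with a warning. Tiles are 128×102 in a 4×5 grid on a 512×512
canvas; the 256×256 center crop follows the stated protocol even though it
discards outer tile regions, and a 2× block-average "resize" option is
provided for comparisons.

# The CNN

Four blocks of [3×3 conv (stride 1, same padding) → batch norm → ReLU →
2×2 max-pool], widths 32/64/128/256, flatten, dense to one logit:
65,536 features for 256×256 input and 453,953 trainable parameters under
the convention that excludes batch-norm affine terms (the layer counts
896 / 18,496 / 73,856 / 295,168 / 65,537 only balance without them; the
full count is also reported). The head is sigmoid + binary cross-entropy —
the single-unit dense output fixes this choice for a binary task.

Training is RMSProp (lr 0.01, α 0.99, ε 1e−8, weight decay 0, momentum 0)
with batch size 1 for 500 epochs in the `full` profile. Batch statistics
are degenerate at batch size 1, so that path normalizes by running
statistics (treated as constants in the backward pass); the `desk` profile
— 64×64 inputs (block-averaged from the 256 crop), batch 8 with proper
batch statistics, lr 1e−3, 15 epochs — is the configuration the test
suite exercises end-to-end on one CPU. Fifteen epochs was fixed once after
observing that the training loss on separable synthetic cohorts plateaus
around epoch 13. All randomness (initialization, example order) derives
from one seed; two runs with the same seed produce identical loss
histories.

Patient-level predictions average the six per-image sigmoid outputs
(majority vote is an option); a positive call requires the aggregate to
*strictly* exceed the threshold, so exact ties resolve to negative. The
evaluation granularity (patients vs images) and the positive class (MCS
by default) are explicit configuration, since neither is determinate from
the source material.

# Baselines and statistics

Screening is a one-way ANOVA per electrode per condition (32 tests) on
per-patient channel-mean ApEn, selecting at uncorrected p < 0.05 — the
rule that yields 7 resting + 8 music = 15 features from the published
table; Bonferroni-adjusted p-values are reported alongside but do not
drive selection. Features are z-scored with training-split statistics
only. The SVM is linear with C = 1 (only "linear" is determinate; C = 1
is the package's fixed choice). The GRNN is Specht's normalized
Gaussian-kernel regression on standardized features (Euclidean distance);
exponents are stabilized by subtracting the per-query maximum, which also
makes the σ → 0 limit exactly the nearest-neighbor rule; σ is selected by
leave-one-out accuracy with ties going to the smallest candidate.

Evaluation: accuracy, sensitivity, specificity, PPV, NPV, F1 from the
confusion matrix, each with an exact Clopper–Pearson CI (the method is not
stated in the source; the exact interval reproduces the printed accuracy
CI (73.47%, 97.89%) for 27/30 to all printed digits, which is what fixed
this choice). Rates with zero denominators are flagged `NA`, never
silently 0. AUC is the trapezoid over all thresholds, equal to the
Mann–Whitney concordance with ties at ½. DeLong's structural-component
estimator provides AUC variances, normal CIs and the paired z test; it is
validated against an independent implementation (pROC) and against a
20,000-rep paired-permutation oracle. At n = 12 the permutation comparison
is dominated not by Monte-Carlo error (±0.003 at 20k reps) but by the
normal approximation itself (~0.02–0.03 measured); the test tolerance of
0.06 reflects that decomposition.

# Problem sizes in the test suite

The suite runs entirely on synthetic data at sizes chosen for a
single-CPU workstation: oracle equivalence on 200 series of n ≤ 500;
statistics oracles at n ≤ 30 with a 20,000-rep permutation comparison;
module tests on 1–8-patient cohorts; and three full desk-profile runs at
20 + 20 patients (the end-to-end recovery block). The acceptance script
additionally generates one 39 + 37 cohort — the published training-set
size — to report cohort structure (Spearman ρ between mean ApEn and CRS-R
in MCS, class means) and one desk end-to-end run keyed to its `--seed`.

# Known limitations

* The synthetic signals are far simpler than clinical EEG (see above);
  absolute classifier performance on them says nothing about patients.
* The full-profile CNN training (500 epochs, batch 1, 256² inputs) is
  runnable but slow on CPU; it is constructed and shape-verified in tests
  but not trained at full scale.
* The EDF writer emits exactly the dialect the package reads (uniform
  sampling rate, 1 s records); it is not a general EDF library.
* GRNN σ selection searches a fixed grid; no continuous optimization.
* The "Two-Way" design is interpreted as one shared network consuming
  images from both conditions; a dual-branch variant is out of scope.
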