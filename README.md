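# docapen

Classification of disorders of consciousness — vegetative state /
unresponsive wakefulness syndrome (VS/UWS) versus minimally conscious
state (MCS) — from the complexity structure of 16-channel EEG.

The package is aimed at researchers in computational neurophysiology who
want a complete, testable reference implementation of an
entropy-topography diagnostic pipeline: channel-wise **approximate
entropy** (ApEn) from resting-state and preferred-music EEG, scalp
**topographic images** fed to a compact **CNN**, and **SVM/GRNN**
baselines on ANOVA-screened features, evaluated with exact binomial CIs,
ROC/AUC and DeLong tests. Because clinical recordings of this kind are
not publicly distributable, a calibrated synthetic-cohort generator
reproduces the statistical structure the analysis depends on, so the
whole pipeline runs and is verified end to end on any machine.

## The statistic at the core

For a series $x_1,\dots,x_L$ with templates
$u_i^{(k)}=(x_i,\dots,x_{i+k-1})$ and Chebyshev distance,

$$C_i^k(r)=\frac{\#\{j: \|u_i^{(k)}-u_j^{(k)}\|_\infty \le r\}}{L-k+1},\quad
\Phi^k(r)=\frac{1}{L-k+1}\sum_i \log C_i^k(r),$$

$$\mathrm{ApEn}(m,r,L)=\Phi^m(r)-\Phi^{m+1}(r),$$

with $m=2$ and $r=0.2\,\mathrm{SD}$: zero for perfectly regular signals,
larger for irregular ones. Lower cortical complexity (lower ApEn) is the
signature of deeper unconsciousness; MCS patients show left-lateralized
ApEn elevation that strengthens under preferred-music stimulation, and
that spatial pattern is what the image classifier learns.

## Worked example

A desk-scale run — 20 synthetic patients per class, 64×64 CNN inputs,
about four minutes on one CPU:

```r
library(docapen)
run <- run_doc_pipeline(pipeline_config(n_vs = 20, n_mcs = 20, seed = 11))
print(run)
#> <doc_run> 20 VS/UWS + 20 MCS patients, seed 11
#>   screened features: 23 of 32
#>   CNN   AUC 1.000  accuracy 91.67%
#>   SVM   AUC 1.000  accuracy 100.00%
#>   GRNN  AUC 0.903  accuracy 91.67%
```

Reading this: ANOVA screening on the training split found 23 of the 32
electrode–condition features separating the classes (the synthetic cohort
is deliberately cleaner than patients); on the 12 held-out patients the
CNN and SVM rank every MCS patient above every VS/UWS patient (AUC 1.0),
the GRNN slightly worse. `run$reports$cnn` holds the full report
(confusion matrix, each rate with its exact 95% CI, ROC points, AUC with
DeLong CI), `run$delong` the pairwise AUC comparisons, and
`run$screening` the per-electrode ANOVA table. The generated cohort also
carries the clinical coupling the analysis expects — in MCS patients,
mean ApEn correlates positively with the CRS-R total (Spearman ρ ≈ 0.4).

Individual stages are ordinary functions — `generate_cohort()`,
`apply_filters()`, `select_segment()`, `segment_epochs()`,
`channel_apen()`, `render_topomap()`, `images_per_patient()`,
`train_cnn()`, `screen_features()`, `train_svm()`, `grnn_predict()`,
`delong_test()` — and a thin CLI wrapper lives at
`inst/scripts/docapen-cli.R` (subcommands `simulate`, `extract`, `run`).

## Package layout

- `R/`, `src/` — implementation (ApEn kernel and CNN engine in C++)
- `inst/extdata/reference_group_apen.csv` — published group-level ApEn
  summary table that parameterizes the generator and the screening check
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles
- `vignettes/docapen-methods.Rmd` — the full methods account: model,
  conventions, calibration, design decisions, limitations
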