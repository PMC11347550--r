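---
title: "Spatial-temporal CT survival modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-temporal CT survival modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with advanced hepatocellular carcinoma (HCC) treated with systemic
therapy undergo serial CT imaging; prognosis depends both on the disease
burden visible at baseline and on how it evolves by the first follow-up.
`ctprog` implements a multimodal prognostic pipeline for overall survival
(OS): representative 2D slices are selected automatically from liver and
lung segmentation masks at two timepoints, embedded by a convolutional
backbone, aggregated over time by a recurrent unit into a radiological risk
score, and fused with a seven-covariate clinical Cox score through a
bivariate Cox model. Because real trial imaging of this kind is not
publicly available, the package ships a synthetic phantom generator with a
*known* hazard so that every stage — slice selection, windowing, the Cox
partial-likelihood training loss, the evaluation statistics, and the
Grad-CAM interpretation — can be exercised and validated end to end.

## The phantom generator

`phantom_config()` / `generate_cohort()` draw, per patient:

* **Anatomy.** One ellipsoidal organ mask per organ (liver in an abdomen
  volume, lung in a chest volume) on a `(z, y, x)` grid, default
  `32 x 64 x 64` voxels at 5 mm axial and 1.5 mm in-plane spacing. Tumors
  are spheres (in mm) placed by rejection sampling so that the *entire*
  grown tumor stays inside the organ; after 100 failed placements the
  radius shrinks by 20% and placement retries. This construction guarantees
  the invariant `tumor mask` ⊆ `organ mask` at both timepoints.
* **Growth.** A per-patient multiplicative radius factor
  `g ~ U(0.8, 1.6)` applied to every tumor at follow-up, so the analytic
  volume ratio is exactly `g^3`.
* **Intensity.** Gaussian i.i.d. HU noise around organ-specific means
  (liver 100 ± 12 HU, lung −700 ± 60 HU, background 0 ± 15 HU), with tumor
  voxels overwritten at a contrasting mean (liver tumor 60 HU, lung tumor
  20 HU). No scanner texture, motion, or contrast-phase model is attempted:
  the noise exists to exercise windowing and the CNN, not to fool a
  radiologist.
* **Clinical covariates.** Histological differentiation as an ordinal code
  0–3 drawn from the multinomial (0.14, 0.74, 0.11, 0.01); six binary
  covariates (NASH/NAFLD, surgery, PVTT, EBRT, TAE/TACE, RFA/MWA) as
  independent Bernoulli draws at the marginal prevalences reported for the
  trial cohort the model family was developed on (0.17, 0.53, 0.17, 0.05,
  0.58, 0.28). Only the marginals are published; the joint distribution is
  a simplification.
* **Outcome.** Event times are exponential with rate
  `h0 * exp(lp)`, `h0 = 1/475` per day (the cohort's median OS is 475
  days), censored by an independent `U(0, 1095)` day horizon. The true
  linear predictor is

  `lp = beta_volume * (log1p(V_base) - log1p(1e4)) + beta_growth * log(V_fu/V_base) + beta_clinical' x`

  with volumes in mm³. The 10 mL reference volume centres the burden term
  near zero for typical multifocal disease; the growth term equals
  `3 * log g` analytically. `beta_clinical` defaults to the published
  clinical coefficients, so the synthetic clinical signal has realistic
  magnitudes. The generator returns `lp` per patient, which is what makes
  recovery experiments and null calibrations possible.

**What passing tests do and do not show.** The phantoms validate the
*machinery*: ranking-loss training recovers a hazard that loads on visible
tumor burden; the evaluation statistics match reference implementations;
the saliency maps land on the lesions that drive the hazard. They say
nothing about performance on real CT, where texture, comorbidity and
segmentation error dominate.

## Preprocessing

The image path mirrors standard CT preparation: linear interpolation along
z to 5 mm slice thickness (`resample_axial()`); window normalization
(`apply_window()`, abdomen WW 400 / WL 0, chest WW 1200 / WL −600, so
`out = clip((HU - WL + WW/2)/WW, 0, 1)`); automatic selection of the three
axial slices with the largest tumor area — falling back to organ area when
fewer than three slices contain tumor, and entirely to organ area when none
do (`select_slices()`); bilinear resize to 224 × 224; per-image
standardization to mean 0 / variance 1. Design points the source procedure
leaves open, fixed here:

* **Tie-break.** Equal areas are broken toward the smaller axial index —
  any deterministic rule works; this one is testable against a brute-force
  oracle.
* **"Tumor present"** means at least one tumor voxel in the slice; no
  minimum-area threshold.
* **Standardization is per image**, after the resize, matching the stated
  order of operations (reshape, then standardize). Constant images (e.g. a
  slice fully outside the window) standardize to all zeros rather than
  dividing by zero.
* **Windowing is applied to the volume** before slice extraction; since the
  transform is pointwise this is equivalent to per-slice application.
* **Missing follow-up chest** scans are imputed by last observation carried
  forward (LOCF): the *processed* lung baseline images are copied, so the
  network sees bitwise-identical tensors for "absent" and "present but
  unchanged" follow-ups.
* Horizontal flips with probability 0.5 (`augment_flip()`) are the only
  augmentation, applied during training only.

## The risk network

`net_config()` / `train_survnet()` implement the convolutional-recurrent
survival network. A shared backbone (four 3 × 3 conv layers with ReLU and
2 × 2 max pooling, global average pooling, and a linear embedding) maps
each slice to a `d`-dimensional embedding; the three slice embeddings per
organ and timepoint are averaged; for the dynamic variant (`rad_d`) a
per-organ LSTM consumes the (baseline, follow-up) sequence and its final
hidden state is kept, while the static variant (`rad_s`) uses the baseline
embedding directly; liver and lung representations are concatenated and
mapped to a scalar log-relative-hazard by linear layers.

Choices made where the architecture description is ambiguous: one backbone
is shared across organs, timepoints and slices (parameter economy —
per-organ backbones would double parameters with no testable benefit at
phantom scale); the temporal units are per organ because concatenation
happens after the temporal stage; the LSTM's *last* hidden state feeds the
head; the head has two linear layers. The backbone works at a reduced
internal resolution (default 32 × 32, reached by exact block-mean pooling
from 224) — at phantom scale the lesion geometry survives the pooling and
the cost drops by two orders of magnitude; the full-resolution path is a
configuration change (`input_size`), not a code change.

**Loss.** The negative log Cox partial likelihood with the Breslow
convention for ties,

`L = -(1/D) * sum_{i: event} [ s_i - log sum_{t_j >= t_i} exp(s_j) ]`,

normalized by the event count `D` so learning rates transfer across cohort
sizes. Risk sets are formed *within each minibatch* (default batch 16,
matching the original optimizer settings of batch 16, Adam, learning rate
5e-5, 200 epochs); batches without events are skipped. This within-batch
approximation is standard for deep survival models and slightly biases the
risk sets; setting `batch_size >= n` gives exact full-batch risk sets for
small cohorts. The analytic gradient is verified against central finite
differences in the test suite, and the loss value against an offset-only
Cox model from the survival package. Two options matter for small-cohort
training, where overfitting and seed-to-seed variance are the dominant
failure modes: an L2 `weight_decay` on all parameters, and `n_models`,
which trains a small deep ensemble of independently seeded networks and
scores patients by the average of the members' training-standardized
scores. At a hundred-odd training phantoms, individual runs of the same
configuration can differ in held-out concordance by ±0.1; the ensemble
average is substantially more stable.

All randomness (initialization, shuffling, augmentation) derives from the
configuration seed; training twice with the same configuration is
bit-identical.

## Clinical score and fusion

`fit_cox()` is a Newton–Raphson maximizer of the Breslow partial
likelihood (step-halving, convergence at gradient max-norm < 1e-8,
explicit diagnostics for separation and constant covariates), returning
the Breslow baseline cumulative hazard alongside the coefficients. It is
deliberately hand-implemented: the package's correctness argument rests on
agreement with the survival package within 1e-6 on random datasets, which
requires the two routes to be independent. The clinical score is the plain
linear predictor `beta' x` with no intercept or centering — the published
formula has one coefficient per covariate, with differentiation entering
as a single ordinal 0–3 code (the exact reference coding behind the
published 0.3747 is not recoverable without the original data; the ordinal
choice matches the one-coefficient form). The published coefficient
vectors are available as `hcc_clinical_coefficients()` and
`hcc_fusion_coefficients()` for scoring new records. Fusion
(`fit_fusion()` / `fuse()`) is a bivariate Cox model on (radiological,
clinical) scores, fitted on the training split and frozen thereafter.

## Evaluation statistics

All of `harrell_c()` (pairwise concordance with half-credit ties and a
Noether-type CI), `km_estimate()` (product-limit and median),
`logrank_and_hr()` (O−E/V chi-square with the HR from a univariate Cox fit
on the group indicator), and `time_dependent_auc()`
(cumulative-case/dynamic-control AUC with Uno-type inverse
probability-of-censoring weights from the Kaplan–Meier estimate of the
censoring distribution; with no censoring it reduces exactly to the
Mann–Whitney statistic) are hand-implemented and pinned against the
survival package on random datasets. Risk stratification uses a strict
`score > cutoff` rule with the cutoff frozen at the training-set median.
The nomogram maps covariate contributions to a 0–100 point scale (100
points = the widest single-covariate contribution range over the fitted
data) and reproduces the direct Cox survival prediction exactly through
the points path; calibration uses quantile bins (default 3 — validation
splits of 30–50 patients would leave deciles empty) against the bin-wise
Kaplan–Meier estimate with Greenwood intervals. The size-based comparator
(`size_based_progression()`) sums the longest in-plane tumor diameter over
organs and calls progression at ≥ +20% over a measurable baseline — a
deliberately simplified RECIST-like stand-in for an adjudicated read
(single merged lesion mask per organ, no new-lesion rule, no 5 mm absolute
minimum).

One reported quantity is intentionally *not* implemented: the "combined"
C-index weighting validation and test sets, whose weighting scheme is not
specified in the source material; guessing it would produce an untestable
number.

## Interpretation

`grad_cam()` computes standard gradient-weighted class activation maps per
slice at the backbone's last convolutional layer, *before* the slice-mean:
channel weights are the spatially averaged gradients of the risk score,
the weighted activation sum is rectified (the published description omits
the rectification step; the standard order — rectify, then normalize — is
used), bilinearly upsampled, and min-max normalized to [0, 1] *after*
upsampling so the bounds are attained exactly. Maps are emitted for both
organ branches. Zero-gradient slices return all-zero maps with a warning
rather than NaNs.

## Pipeline, splits and determinism

`split_cohort()` assigns whole recruiting centers (or patients) to
train/validation/test with floored validation/test counts and the
remainder to training — mirroring center-level assignment followed by an
8:2 development split, i.e. overall fractions (0.64, 0.16, 0.20).
`run_pipeline()` chains generation, pack assembly, training of both
imaging variants, the clinical fit, fusion, cutoff freezing and evaluation
of all five variants per split, and is byte-reproducible under fixed
seeds. A thin command-line dispatcher (`inst/cli/ctprog.R`) exposes each
stage (`simulate`, `preprocess`, `train`, `fit-clinical`, `fuse`,
`evaluate`, `explain`, `run`) for shell use.

## Problem sizes used in the validation suite

The automated suite runs entirely on phantoms, sized to hold oracle and
recovery properties while staying desk-scale: oracle-equivalence checks
use 50 random survival datasets of 20–45 patients and 200 random mask
pairs; coefficient recovery uses n = 2000 records; the imaging recovery
experiment trains an ensemble of three scaled networks (32 × 32 internal
resolution, batch-48 risk sets, weight decay, 30 epochs) on 120 phantoms
with `beta_volume = 1.5` and evaluates on 80 held-out phantoms;
replicate-level properties (fusion vs clinical-only, model vs size-based
stratification, Grad-CAM localization) use 10–100 seeded small
replicates with all fitted models frozen before evaluation, mirroring
the frozen-cutoff protocol of the pipeline. For calibration of
expectations: the concordance of the *true* linear predictor on held-out
phantoms — the information-theoretic ceiling — is about 0.75–0.77 under
these conditions, and a hand-crafted tumor-area feature extracted from
the same 12 selected slices reaches about 0.68, so recovery results in
the low-to-mid 0.6s indicate the network is extracting most of the
burden signal the slice representation carries.

## Known limitations

* Phantom realism is intentionally minimal (see above); absolute
  performance numbers on phantoms do not transfer to real CT.
* In the phantom world the size-based comparator is *stronger* than it is
  in practice: it reads ground-truth masks, and because the growth factor
  is patient-global, the ≥ +20% diameter rule is nearly a sufficient
  statistic for a growth-driven hazard. Comparisons of the learned model
  against it on phantoms therefore favor the size rule, the opposite of
  the clinical setting, where progression calls are noisy human reads and
  the model sees more than size.
* Training a convolutional network from scratch on ~100 phantoms sits in
  a regime where memorization of patient-identifying anatomy (organ-shape
  jitter) competes with the prognostic signal; weight decay and seed
  ensembling mitigate but do not remove this, and held-out concordance
  stays a few points below the slice-representation ceiling.
* The within-batch partial likelihood is biased for small batches; use
  full-batch mode for cohorts of a few hundred.
* `fit_cox` handles neither stratification, time-varying covariates, nor
  regularization, and refuses separated designs rather than penalizing
  them.
* The IPCW AUC assumes censoring independent of the score within the
  cohort (satisfied by construction in the phantoms).
* Differentiation coding and the original fusion scale cannot be verified
  against the private data; the published coefficient vectors are
  reproduced verbatim and exercised arithmetically.
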