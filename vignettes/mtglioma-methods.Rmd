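---
title: "Methods: multi-task glioma genotyping and grading from multimodal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task glioma genotyping and grading from multimodal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two biomarkers drive preoperative decisions in adult diffuse glioma:
isocitrate dehydrogenase (IDH) mutation status and WHO grade (here
binarized: lower 2–3 vs higher 4). Both are normally obtained invasively.
Multimodal MRI offers a non-invasive surrogate: IDH-mutant, lower-grade
tumors often show the *T2-FLAIR mismatch sign* (hyperintense on T2,
centrally suppressed on FLAIR), and necrotic-core size tracks grade. The two
labels are strongly coupled — wildtype tumors are mostly high grade — so a
multi-task model can exploit one task's signal for the other.

`mtglioma` implements a multi-task architecture for this problem:

1. **MFEB** — a mismatch feature extraction block. Each of T2 and FLAIR is
   "overviewed" by average+max pooling to half resolution, passed through a
   chain of shared-weight dilated blocks (kernels 7→5→3, dilation 3), mapped
   back to full resolution by a transposed convolution and squashed by a
   sigmoid into a per-voxel weight in (0,1). The mismatch map is
   `x_tf = w(t2)·t2 − w(flair)·flair`. Because one parameter set serves both
   branches, identical inputs cancel exactly and swapping inputs negates the
   map; a `bypass` flag reduces the block to plain subtraction (the
   "without MFEB" ablation).
2. **Adapter-tuned 3D transformer encoder.** The mismatch map is
   concatenated with the four modalities; a strided-conv patch embedding
   (kernel = stride = 16 at reference scale) produces an (8,8,8)×384 token
   grid. A pretrained single-channel patch-embed kernel can be inflated to
   five channels by replication with 1/5 scaling, which preserves the
   response to channel-constant inputs. Each transformer block carries a
   **multi-view adapter**: the block's input tokens are pooled to a channel
   vector, bottlenecked to `embed/8` features, combined bilinearly with a
   bottlenecked 101-element tabular vector (99 radiomic-like + age + sex)
   into one sigmoid gate per channel, and the gated (width-preserving
   linear transform of the) token grid is fed to a **dilated group
   convolution block** (three parallel branches, kernels 7/5/3, dilation 3,
   `embed/8` groups) whose pointwise output has query/key/value width
   `3·embed`. That fused tensor is *added* to the block's QKV — so zeroed
   adapters reproduce the plain backbone exactly, which is both the
   "without MVAdapter" ablation and a strong correctness oracle.
3. **Losses.** Per task, the loss on the predicted true-class probability
   `y_t` is `−α(1−y_t)^γ log(y_t) + β·H(y_t)` with γ = 2 and α the
   training-split negative/positive ratio (applied to positive-class
   samples). The regularizer `H` is implemented literally as printed in the
   source method — the entropy of `y_t`, not label-conditioned cross-entropy
   — with a `form = "conventional"` switch for `−log(y_t)`. The two task
   losses combine through trainable uncertainty weights,
   `L = Σ L_i/(2γ_i²) + Σ log γ_i`, parameterized as `log γ_i` so positivity
   is structural; at the γ = (1,1) initialization this is the plain mean.

## Why the neural layers are hand-built

No deep-learning framework for R ships with the supported environment, so
the package includes a small reverse-mode autodiff tape (`R/autograd.R`)
with Rcpp kernels for 3D convolution. Direct (no-im2col) kernels are used
because materializing im2col columns for kernel-7 dilated convolutions
costs tens of MB per call; the direct kernels stream channel-planar copies
with contiguous inner loops. Every operator, and the full composed model,
is verified against central-difference gradients in the test suite — that
suite is the load-bearing correctness argument for everything downstream.

## The phantom generator: what it emulates, and what it does not

Real cohorts (hundreds of subjects, four modalities, expert ROIs) cannot be
bundled, so `generate_cohort()` builds a synthetic stand-in whose *stated
world* mirrors the source cohorts' structure:

* class marginals default to 20% IDH-mutant and 80% higher-grade with
  `P(lower grade | mutant) = 0.9`, matching the published cohort table where
  82/394 training subjects are mutant, 317/394 are grade 4, and mutation
  co-occurs with lower grade;
* each subject is a brain ellipsoid containing one tumor of three concentric
  compartments (necrotic core = 1, enhancing = 2, edema = 3). The core is
  kept *strictly* inside the enhancing rim even after voxelization (boundary
  core voxels are relabeled);
* the IDH signal is a tumor-interior T2-up/FLAIR-down shift of
  `±0.5·mismatch_effect` (default 2, in pre-standardization intensity
  units) — i.e. a planted mismatch sign;
* the grade signal inflates necrotic-core volume by `1 + necrosis_effect`
  (default 2);
* intensities get additive Gaussian noise (`noise_sd = 0.2`, roughly 10–20%
  of the tissue contrasts) and are z-scored within the brain mask per
  modality, since the source pipeline never states a normalization.

One deliberate non-physical choice: baseline FLAIR tracks baseline T2 with a
compartment-*independent* offset. With coupled labels, any
compartment-dependent T2−FLAIR baseline contrast would leak a grade-mediated
IDH signal through core size, violating the requirement that
`mismatch_effect = 0` produce indistinguishable classes. The phantom
therefore does not emulate true FLAIR fluid suppression, MR physics, bias
fields, registration error, or scanner variation — a green test establishes
that the architecture recovers *planted, well-separated* signals, not
clinical performance.

The tabular table plants `n_informative` (default 10) of 99 noise columns
with an `effect`-SD class shift, split between the tasks; age is shifted
+10 years for wildtype (older patients are more often wildtype) and sex is
independent noise.

## Feature selection

`lasso_select()` follows the published recipe: five stratified folds; per
fold an L1 path (50 log-spaced penalties) fit on 4/5 and scored by held-out
deviance; nonzero coefficients pooled across folds by union (intersection
optional); an unpenalized refit on the pooled survivors assigns Wald
p-values; survivors with p > 0.05 are dropped; age and sex are always
retained at combination. Two decisions the source leaves open: the p-filter
runs *after* pooling, and "Lasso regression" is read as gaussian-family
regression on the 0/1 label (the standard radiomics reading). The logistic
variant is available but its unpenalized refit degenerates under complete
separation, which is exactly the regime of strongly planted features.

## Training, evaluation, explanation

Training follows the published recipe at reference scale: Ranger optimizer
(RAdam + Lookahead, k = 6, α = 0.5 — implemented in the package, since no R
Ranger exists), initial learning rate 2e-5, cosine decay to zero, batch
size 4 via gradient accumulation, 80/20 train/test split with 15% of
training data for validation, both splits stratified jointly on both
labels, augmentation by axis flips, 90° rotations (interpolation-free, so
masks transform exactly), integer shifts, Gaussian noise and intensity
scaling. Batch norm uses per-sample spatial statistics during training
(batch-size-1 batch norm) with running moments for eval — a simplification
of cross-sample batch statistics that keeps the hand-rolled engine simple.
The best-validation-loss state is kept. The backbone is frozen by default
(adapters-only fine-tuning of a pretrained encoder). The scaled-down test
configuration has no pretrained weights to protect, so it unfreezes the
backbone and trains from scratch with Adam at a constant 3e-3 — the
reference 2e-5 is a *fine-tuning* rate — and drops the 90° rotation
augmentation, which slows optimization of a small model far more than it
regularizes it. Two lessons from tuning are worth recording: (i) evaluation
must normalize with the same per-sample statistics as training (the
instance-norm point above) — EMA eval moments inverted held-out rankings;
(ii) recipe choices must be probed at the scale where the signal is
physically accessible: at 16-cube volumes even oracle statistics cannot
detect the planted effects, so only 32-cube experiments are informative.

Evaluation reports AUC (rank statistic with mid-rank ties), accuracy
`(TP+TN)/(TP+TN+FP+FN)` and F1 `2TP/(2TP+FP+FN)` from confusion counts at
threshold 0.5, each with 95% percentile-bootstrap confidence intervals over
subjects (2000 resamples at reference, fewer in tests). A single-class test
set yields `AUC = NA` with an explanatory note rather than a number.

Grad-CAM uses the last transformer block's output token grid as the target
layer: channel weights are spatial means of the chosen class logit's
gradient, the ReLU-ed weighted channel sum is upsampled (nearest-neighbor)
to patch resolution and normalized to [0,1]; an all-zero gradient is
flagged rather than silently normalized.

## Numerical and design choices worth knowing

* `qkv_dim` is `3·embed_dim` (1152 at reference). The source text prints
  channel count "1,052" while simultaneously requiring consistency with the
  QKV dimensions; consistency wins, and the printed value remains selectable
  for standalone use of the fused branch.
* Probability clamp ε = 1e-7; LeakyReLU slope 0.01; dropout 0.1; dilated
  block FFN expands ×2; the transposed convolution is kernel 2, stride 2.
  None of these are stated in the source; all are configurable.
* Pooling "to half resolution" is window-2/stride-2; odd spatial dims are an
  error rather than an implicit pad.
* One adapter (MVAdapter + DGCB) per transformer block, consuming that
  block's input tokens; the source shows a single figure without stating
  multiplicity.
* Patch extraction centers on the ROI bounding-box midpoint and zero-pads
  out-of-volume regions so the midpoint stays exactly at the patch center.
* Checkpoints are a flat named-tensor binary archive plus JSON manifest;
  batch-norm running moments and feature-standardization statistics ride in
  the same binary file so save/load round trips are bit-exact.

## Known limitations

The phantom's simplicity means headline clinical metrics are out of reach by
design; the package's empirical claims are confined to what its tests
compute (loss identities, algebraic reductions, shape contracts, planted
signal recovery at scaled-down size, selection recovery and calibration,
metric identities, explanation sanity). Training at full reference scale
(128³, 384 channels, 12 blocks) is implemented but CPU-impractical; the
scaled configuration (32³, embed 48, 2 blocks, patch 8, MFEB width 4) is
the supported desk-scale regime.
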