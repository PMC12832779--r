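# mtglioma

Joint, non-invasive prediction of glioma **IDH genotype** (mutant vs
wildtype) and **WHO grade** (lower 2–3 vs higher 4) from multimodal 3D MRI
(T1, T1CE, T2, FLAIR) plus tabular radiomic and clinical features — for
researchers who want the full multi-task architecture as inspectable,
dependency-light, tested R code.

## What it implements

* **MFEB** — a learned T2-FLAIR mismatch extractor. Each modality is pooled
  to half resolution (avg ⊕ max), passed through shared-weight multi-scale
  dilated blocks (kernels 7→5→3, dilation 3), upsampled and squashed to a
  per-voxel weight w ∈ (0,1); the mismatch map is
  `x_tf = w(t2)·t2 − w(flair)·flair`. A bypass flag reduces it to plain
  subtraction.
* A **3D vision-transformer encoder** (foundation-segmentation-model
  stand-in: patch 16, embed 384, (8,8,8) token grid at 128³ reference
  scale) fine-tuned parameter-efficiently: per block, a **multi-view
  adapter** gates the token grid by a bilinear combination of pooled image
  features and 101 tabular features (both bottlenecked to embed/8 = 48),
  a **dilated group convolution block** lifts the gated grid to QKV width
  (3·embed = 1152), and the result is added to that block's query/key/value.
* **Losses**: per task `−α(1−y_t)^γ log y_t + β·H(y_t)` with γ = 2 and α the
  training-split class ratio, combined by trainable uncertainty weights
  `Σ L_i/(2γ_i²) + Σ log γ_i`.
* **Feature selection**: per-task 5-fold cross-validated Lasso, per-fold
  penalty by held-out deviance, pooled by union, Wald p > 0.05 filtered,
  age/sex always kept.
* **Evaluation**: rank AUC, ACC, F1 with percentile-bootstrap 95% CIs;
  **Grad-CAM** volumes from the last block's token grid.
* A **synthetic glioma phantom** cohort generator (three-compartment
  ellipsoidal tumors, Table-1-like class marginals, planted mismatch and
  necrosis signals) so the whole pipeline is testable offline.

All neural layers run on a small reverse-mode autodiff engine included in
the package (Rcpp direct-convolution kernels + BLAS) — no deep-learning
framework required. Gradients are verified against central differences in
the test suite.

## Worked example

```r
library(mtglioma)

co   <- generate_cohort(phantom_spec(80, grid_size = 32, seed = 101))
test <- generate_cohort(phantom_spec(60, grid_size = 32, seed = 202))

cfg <- train_config(
  encoder = encoder_config(input_size = 32L, patch_size = 8L,
                           embed_dim = 48L, n_blocks = 2L, n_heads = 6L,
                           freeze_backbone = FALSE),
  mfeb_width = 4L, learning_rate = 3e-3, epochs = 7L,
  optimizer = "adam", schedule = "constant",
  augmentation = list(flip = TRUE, shift = TRUE, intensity = TRUE,
                      noise = TRUE),
  seed = 1L, test_fraction = 0)

ck  <- train(co, cfg)
rep <- evaluate(ck, test, n_boot = 500L, seed = 1L)
print(rep)
```

```
idh     AUC 1.000 [1.000-1.000]  ACC 1.000 [1.000-1.000]  F1 1.000 [1.000-1.000]
grade   AUC 0.991 [0.965-1.000]  ACC 0.900 [0.833-0.967]  F1 0.935 [0.878-0.979]
```

(Output of this exact script; numbers are for planted phantom signals —
mutant subjects carry a mismatch-sign shift of 2 intensity SD and
high-grade subjects a 3× necrotic core — and say nothing about clinical
data.) `gradcam(ck, test[[1]], task = "grade")$map` returns a [0,1]
attention volume whose mean is higher inside the tumor mask than outside.

A command-line interface covers the same pipeline:

```sh
Rscript inst/cli/mtglioma.R simulate --n 40 --grid 32 --seed 7 --out cohort/
Rscript inst/cli/mtglioma.R select-features --cohort cohort/ --out sel.json
Rscript inst/cli/mtglioma.R train --cohort cohort/ --config ref.yaml --out ckpt/
Rscript inst/cli/mtglioma.R eval --checkpoint ckpt/ --cohort cohort/ --out report.json
Rscript inst/cli/mtglioma.R explain --checkpoint ckpt/ --cohort cohort/ --task idh --out cam.nii.gz
```

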