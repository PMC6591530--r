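# dwmacnn

Automated detection of **diffuse white matter abnormality (DWMA)** on
T2-weighted neonatal brain MRI, by patch-based deep convolutional neural
networks — implemented from scratch in R/RcppArmadillo, with a synthetic
phantom study standing in for clinical cohorts that cannot be shared.

## Who this is for, and what it does

Very preterm infants scanned at term-equivalent age frequently show
diffusely increased T2 signal in unmyelinated white matter. The burden of
this abnormality, normalised by head size as the DWMA-to-brain ratio
(DBR = DWMA volume / brain volume), is a candidate predictor of later
cognitive outcome — but manual delineation is slow and rater-dependent.
`dwmacnn` treats detection as voxel classification: every white-matter
voxel is labelled DWMA or normal from the small 2D axial patch centred on
it,

* `build_architecture(n)` — compact CNNs for patch sizes n ∈ {7, 9, 13, 17}:
  3×3 valid convolutions with ReLU, `a = max(0, X * W)`, each followed by
  batch normalisation `BN(x) = γ (x − μ_B)/√(σ_B² + ε) + β` and 2×2
  stride-1 max pooling; then a 10-neuron fully-connected layer, batch
  norm, and a 2-way softmax (12 layers for n = 13, 17; 9 for n = 7, 9).
* `train_cnn()` — mini-batch SGD (batch 256, learning rate 0.1) with
  Nesterov momentum, Glorot-uniform initialisation, cross-entropy loss
  `H(W) = −(1/N) Σ [y log p + (1 − y) log(1 − p)]`, ≤ 20 epochs with
  early stopping on a loss plateau. Forward and backward passes are
  hand-built (and finite-difference-checked in the test suite).
* `zscore_normalize()` / `gold_standard_dwma()` — the labeling rule:
  after z-scoring over the brain, a white-matter voxel is DWMA iff its
  intensity ≥ mean + 1.4 SD of cerebral tissue; `clean_mask()` removes
  isolated components as a deterministic stand-in for manual cleanup.
* `generate_phantom()` / `generate_cohort()` — synthetic neonatal T2
  volumes (ellipsoidal tissue shells, periventricular DWMA lesions,
  Rician noise at configurable SD; mean cerebral intensity calibrated to
  225 so noise SDs {10, …, 30} give SNRs 22.5 … 7.5) with exact
  ground-truth masks.
* `run_validation()` / `run_simulation_study()` — leakage-free
  subject-level designs (LOSO, k-fold, holdout) reporting per-subject
  Dice and balanced accuracy, DBR, Bland–Altman agreement, and paired
  t-tests between models; linear-SVM and MLP baselines via
  `svm_factory()` / `mlp_factory()`.

Results are tibbles throughout; fitted models and reports have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(dwmacnn)

spec <- build_architecture(13)
forward_shape_trace(spec)
#>    layer kind            channels height width  flat
#>  1     1 convolution            8     11    11   968
#>  3     3 max_pool               8     10    10   800
#>  9     9 max_pool              16      4     4   256
#> 10    10 fully_connected       10      1     1    10
#> 12    12 softmax                2      1     1     2
```

The trace is the printed feature-map chain of the 12-layer network: eight
11×11 maps after the first convolution, sixteen 4×4 maps after the last
pool, a 256-dimensional flattened vector into the fully-connected stage.

A small end-to-end study — three phantoms (64×64×12 voxels), Rician noise
SD 10, leave-one-subject-out, the 13×13 CNN at 8 epochs — runs in about
two minutes:

```r
cfg <- experiment_config(
  n_subjects = 3,
  phantom = phantom_spec(volume_shape = c(64L, 64L, 12L)),
  noise_sds = 10, patch_sizes = 13,
  training = training_config(max_epochs = 8),
  design = design_loso(), master_seed = 42)
study <- run_simulation_study(cfg)
study$cells$report[[1]]
#> <dwma_eval> 3 held-out subject evaluations (loso)
#>   dice              0.9656 (0.0177)
#>   balanced_accuracy 0.9713 (0.0185)
#>   DBR agreement: mean diff -1.15e-03, limits [-3.04e-03, 7.46e-04]

tidy(study$cells$report[[1]])
#>   subject_id  fold  dice balanced_accuracy dbr_pred dbr_gold
#> 1 sim01          1 0.948             0.954   0.0209   0.0229
#> 2 sim02          2 0.965             0.970   0.0262   0.0276
#> 3 sim03          3 0.984             0.990   0.0261   0.0262
```

Each row is one held-out subject: the Dice overlap and balanced accuracy
of the predicted DWMA mask against the threshold-rule gold standard over
white matter, and the predicted vs. gold DWMA-to-brain ratios (here ~2–3%
of brain volume, with predicted DBR tracking gold to ~1e-3). At the full
study scale (10 phantoms, 96×96×20, ≤20 epochs) mean Dice at SNR 22.5 is
≈ 0.99.

A thin command-line interface wraps the same functions
(`simulate`, `preprocess`, `train`, `segment`, `run-study`):

```sh
cli=$(Rscript -e 'cat(system.file("cli/dwmacnn", package = "dwmacnn"))')
Rscript "$cli" simulate --n-subjects 10 --noise-sd 10 --seed 7 --out phantoms/
```

## Package layout

* `R/phantom.R` — phantom specification, Rician noise, SNR, cohorts
* `R/preprocess.R` — z-score normalisation, gold-standard rule, cleanup
* `R/patches.R` — per-voxel patch datasets, subject-grouped splits
* `R/architecture.R`, `R/train.R`, `src/engine.cpp` — the four CNNs and
  the from-scratch training/inference engine
* `R/evaluation.R` — Dice, balanced accuracy, DBR, Bland–Altman,
  validation designs
* `R/baselines.R` — linear SVM (soft-margin grid) and MLP comparators
* `R/workbench.R` — end-to-end seeded simulation studies
* `vignettes/dwma-detection.Rmd` — model, assumptions, design decisions,
  limitations
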