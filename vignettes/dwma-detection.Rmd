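---
title: "Patch-based CNN detection of diffuse white matter abnormality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based CNN detection of diffuse white matter abnormality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dwmacnn)
```

## The problem

Diffuse white matter abnormality (DWMA) appears in a majority of very
preterm infants scanned at term-equivalent age as regions of abnormally
high signal in the unmyelinated white matter of T2-weighted MRI. Its
extent, usually summarised as the DWMA-to-brain volume ratio (DBR), is a
candidate prognostic biomarker for later neurodevelopment, but manual
delineation is slow and subjective. `dwmacnn` frames detection as
voxel-wise classification: every white-matter voxel is assigned to the
DWMA or normal class from the small 2D axial patch centred on it, by a
compact deep convolutional network. This vignette documents the model, the
design decisions behind the implementation, and what the synthetic
validation can and cannot show.

## Voxel classification model

For a patch size $n \in \{7, 9, 13, 17\}$ the network is a fixed sequence
of blocks. Each convolutional block is a 3×3 valid convolution with stride
1 and ReLU activation,

$$a_{\mathrm{conv}} = \max(0,\; X * W_{\mathrm{conv}}),$$

followed by batch normalisation

$$\mathrm{BN}_{\gamma,\beta}(x_i) = \gamma\,\frac{x_i - \mu_B}{\sqrt{\sigma_B^2 + \epsilon}} + \beta$$

over the mini-batch $B$ (per feature map), and a 2×2 max pool with stride
1. A valid 3×3 convolution shrinks each spatial side by 2 and the stride-1
pool by 1, which fixes the whole shape chain; for $n = 13$:
13 → 11 (conv, 8 maps) → 10 (pool) → 8 (conv, 8 maps) → 7 (pool) → 5
(conv, 16 maps) → 4 (pool), flattened to a 256-dimensional vector. A
10-neuron fully-connected ReLU layer, batch normalisation, and a 2-way
softmax complete the 12-layer network; the two shallower networks (for
$n = 7, 9$) drop one convolutional block and have 9 layers. Biases are
omitted from every convolution and the fully-connected layer because the
following batch-normalisation shift absorbs them; the softmax layer keeps
its bias. Convolution is implemented as cross-correlation, the deep
learning convention; the printed shape chain above is only consistent
with valid (unpadded) convolutions, which settles that choice.

`count_parameters(build_architecture(13))` reports 4,466 trainable
parameters (weights, batch-norm scale/shift pairs, softmax bias). We note
that no standard counting convention applied to this layer table yields
the 6,264 sometimes quoted for a network of this shape; the package
reports its own count.

Training minimises the cross-entropy

$$H(W) = -\tfrac{1}{N}\sum_i \left[ y_i \log p(y_i \mid X_i; W) + (1 - y_i)\log(1 - p(y_i \mid X_i; W)) \right]$$

by mini-batch stochastic gradient descent (batch size 256) with Nesterov
momentum and Glorot-uniform initialisation, at a constant learning rate of
0.1, for at most 20 epochs. All of this — forward and backward passes for
convolution, batch normalisation, pooling, the fully-connected and softmax
layers, and the optimiser — is implemented from scratch in RcppArmadillo;
correctness is established in the test suite by brute-force convolution
oracles and central finite-difference gradient checks on every
parameterised layer.

### Choices the recipe leaves open

* **Momentum coefficient** is not pinned down by the recipe; the default is
  0.9 (configurable), the value practitioners reach for first.
* **Early stopping** is specified as "three consecutive epochs return the
  same loss". Exact floating-point equality of SGD epoch losses
  essentially never happens, so the condition is operationalised as the
  last `early_stop_patience = 3` epoch losses lying within
  `loss_tolerance = 1e-4` of each other.
* **Batch-norm inference statistics.** Only the training-time transform is
  defined by the model; at inference the package uses exponential running
  averages (momentum 0.99) of the batch statistics, bias-corrected by
  $1 - 0.99^{t}$ after $t$ update steps so that short trainings are not
  dragged toward the zero initialisation.
* **Numerical guards:** $\epsilon = 10^{-5}$ in batch normalisation;
  softmax is computed with the max subtracted; log-probabilities are
  floored at $10^{-12}$ inside the loss only.
* **Decision threshold** is 0.5 (the argmax of the 2-way softmax),
  exposed as a parameter of `predict_volume()` for ROC-style analyses but
  fixed in all headline metrics.
* **Training-set size.** `training_config()` caps the patches per fit at
  `max_train_patches = 25000`, drawn as a seeded, stratified,
  prevalence-preserving subsample (no class rebalancing — imbalance is
  handled in the metrics, not the data). A leave-one-subject-out fold at
  the shipped phantom scale pools ~1.7 × 10^5 patches; the cap keeps a
  full study tractable on one desktop core while leaving ~1,500 DWMA
  patches per fit, ample for this contrast. Set it to `NULL` to train on
  everything.

## Patches and labels

Patches are 2D and axial — the classifier input is explicitly a planar
$n \times n$ neighbourhood, not a 3D block — and are extracted for every
white-matter voxel, so a subject contributes exactly as many samples as it
has white-matter voxels (~10^5 on clinical volumes). Neighbourhoods that
leave the volume are zero-padded; zero is the background value of a
z-scored image, so padding is indistinguishable from out-of-brain
background. Patch sets are lazily indexed (centres plus a reference to the
source volume) and materialised on demand, which keeps memory linear in
the number of voxels rather than patches × patch area.

Only white-matter voxels are classified, at training and at inference:
the two classes are DWMA versus *normal white matter*, so voxels outside
the white-matter mask are out of scope by definition.

## Gold-standard labels

Labels come from the intensity rule used for expert annotation: after
z-score normalisation of the T2 volume over the brain mask (population
SD), a white-matter voxel is DWMA iff its intensity is **greater than or
equal to** $\mu_c + 1.4\,\sigma_c$, where $\mu_c, \sigma_c$ are the mean
and SD over cerebral tissue. Two points were genuinely open:

* *Which voxels define the cerebral statistics.* The package computes them
  over the whole brain mask (the rule contrasts white-matter voxels
  against cerebral tissue generally), with `stats_over = "wm"` available
  as a switch.
* *Cleanup of isolated voxels.* Expert raters removed isolated false
  positives by hand; a repository needs a deterministic stand-in, so
  `clean_mask()` deletes 26-connected components below
  `min_component_voxels = 5`. It never adds voxels, and the default of 5
  is small enough to leave any plausible lesion untouched.

The rule is invariant to affine rescaling of the raw intensities (the
z-score absorbs it), which the tests assert directly.

## The phantom generator

The in-vivo cohorts behind this line of work are not shareable, so the
package ships a simulation in their place, and the generator's defaults
*are* the study conditions. Each phantom is a 96 × 96 × 20 voxel volume
(1 × 1 × 2 mm): concentric ellipsoidal shells form a cortical grey-matter
rim around a white-matter interior with two CSF-filled lateral ventricles;
three ellipsoidal DWMA lesions sit in the periventricular white matter
(anterior and posterior of the ventricles), jittered in-plane per subject.
Class intensities are Gaussian around means CSF 340, GM 190, WM 225 — the
neonatal T2 ordering, in which unmyelinated white matter is brighter than
cortex and CSF is brightest — and the DWMA mean defaults to the
white-matter mean plus 2.0 within-brain SDs, so lesions clear the 1.4-SD
labeling threshold with margin. The within-class SD defaults to 2% of the
class mean: large enough to give each tissue texture, small enough that
the 1.4-SD rule recovers the simulated truth exactly on the noiseless
image (a property the test suite asserts; at 5% within-class spread the
rule mislabels several percent of normal white matter, defeating the
simulation's own ground truth). Image noise is then supplied explicitly by
the Rician stage: each voxel $A$ becomes $\sqrt{(A+n_1)^2 + n_2^2}$ with
$n_1, n_2 \sim \mathcal{N}(0, \sigma^2)$, the magnitude-MRI noise model,
which the tests check against its Rayleigh limit on zero signal.

After composition the volume is rescaled so the mean cerebral intensity is
exactly 225 — the one scale on which the noise sweep
$\sigma \in \{10, 15, 20, 25, 30\}$ maps to SNRs
$\{22.5, 15, 11.25, 9, 7.5\}$ as printed in the source study's sweep.
(That study prints 11.3 and 7.6 for the middle and last entries;
$225/20 = 11.25$ and $225/30 = 7.5$, so its rounding is internally
inconsistent and the package reports computed SNR instead of matching
7.6.)

What the phantom deliberately does **not** model: cortical folding,
myelination gradients, bias fields, partial-volume mixing at tissue
boundaries, motion, or multi-contrast acquisition. Passing the simulation
therefore shows that the architecture, training recipe, labeling rule and
evaluation harness are implemented correctly and that the classifier
solves the stated detection problem at realistic noise levels — it does
not certify clinical performance on real neonatal scans, whose DWMA
contrast is far subtler than a 2-SD offset.

## Validation designs and metrics

`run_validation()` supports leave-one-subject-out, subject-level k-fold
(seeded random fold assignment, no forced class balance) and explicit
holdout designs. Splits are by subject, never by patch; every design
audits that no subject appears on both sides of a fold. Metrics are
computed per held-out subject and then averaged (matching per-subject
mean ± SD reporting), not pooled over voxels:

* **Dice** $2|A\cap B| / (|A| + |B|)$; two empty masks are defined to
  agree perfectly (Dice 1, with a warning) — a convention needed only for
  degenerate inputs.
* **Balanced accuracy** $\tfrac12(TP/P + TN/N)$ over white-matter voxels,
  the right accuracy under heavy class imbalance.
* **DBR**, the DWMA-to-brain voxel-count ratio, and **Bland–Altman**
  agreement (mean difference ± 1.96 sample SD) between predicted and gold
  DBR across subjects.
* **Model comparison** uses a *paired* two-sided t-test on per-subject
  metrics — paired because the same held-out subjects are scored under
  both models; identical inputs (zero-variance differences) are reported
  as degenerate rather than given a fabricated p-value.

The comparator baselines are a linear-kernel soft-margin SVM on flattened
patches, with C searched over the 11 even powers of two from $2^{-10}$ to
$2^{10}$, and a small fully-connected network (hidden sizes 64 and 10,
ReLU, softmax) trained with the same SGD recipe; the latter stands in for
a deep-neural-network comparator whose exact published architecture is
not available, and its sizes are this package's choice. The SVM's C is,
by default in `train_svm_baseline()`, chosen on the evaluation data
passed to it — replicating the benchmarked procedure faithfully — but the
documentation flags this as optimistic and `svm_factory()` uses an inner
split of the training patches instead. SVM training subsamples to at most
5 × 10^4 patches per class; quadratic-cost solvers do not scale past
that, and the comparison stays subject-held-out.

## Study scales and reproducibility

Two named scales ship as presets: `paper_scale` — 10 phantoms at
96 × 96 × 20, leave-one-subject-out, the full ≤20-epoch recipe — used by
the acceptance script and the heavy acceptance tests (one such study is
roughly 8–10 minutes on a single core), and `test_scale` — 2 phantoms, 3
epochs — for smoke runs. All randomness descends from one master seed
through a deterministic integer derivation (subject seeds, lesion jitter,
noise draws, fold assignment, weight initialisation, shuffling,
subsampling), so a study is a pure function of its configuration: the
workbench tests assert byte-identical summaries across reruns. Training
seeds are derived independently of the noise level, so the noise sweep
retrains the same initialisations on the same anatomies with only the
corruption changed.

## Known limitations

* The phantom's lesion contrast is generous by design; absolute Dice
  values on it say little about in-vivo Dice.
* 2D axial patches ignore through-plane context; thick-slice acquisitions
  motivate this, but isotropic data might favour 3D blocks (out of scope
  here).
* The engine is CPU-only and double-precision; it is sized for ~10^5-patch
  studies, not for training on millions of patches.
* `clean_mask()` is a deterministic proxy for expert correction; it
  removes salt noise but cannot reproduce judgment calls near lesion
  boundaries.
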