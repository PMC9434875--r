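---
title: "Supervised autoencoders with structured sparsity: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised autoencoders with structured sparsity: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(saefs)
```

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and the known limits.

## The model

A supervised autoencoder (SAE) couples three components on a samples ×
features table `X` (m × d) with labels `y ∈ {1..k}`:

* an **encoder** `d → h (ReLU) → k`, producing a latent code `Z` whose
  dimension equals the number of classes;
* a **decoder** mirroring the encoder, `k → h (ReLU) → d`, producing a
  reconstruction `X̂` in the preprocessed space;
* a **softmax head** applied directly to `Z`, turning the latent coordinates
  into class probabilities.

Training minimises the composite criterion

$$\mathrm{Loss}(W) \;=\; \phi(Z, Y) \;+\; \lambda\, \psi(\hat X - X)
\quad \text{s.t.} \quad \lVert W_1 \rVert_{1,1} \le \eta,$$

where $\phi$ is the mean softmax cross-entropy, $\psi$ the reconstruction
loss, and $W_1$ the d × h first encoder layer. The reconstruction term acts
as a label-free regulariser: the latent code must retain enough information
to rebuild the sample, which stabilises small-cohort training where a plain
classifier of the same architecture overfits. Unlike variational
autoencoders, no parametric prior is imposed on the latent space — its
geometry is shaped by the labels alone, which is what makes the latent plot
directly interpretable (one axis per class, samples clustering by
diagnosis).

Two reconstruction losses are available. The default is the Huber (smooth
ℓ1) loss — quadratic for residuals below `huber_delta`, linear above — so a
handful of aberrant samples cannot dominate the reconstruction gradient; the
squared-error variant (`recon_loss = "l2"`) is the classical comparator. The
package's tests quantify the difference: growing an injected outlier 10×
grows the Huber term ≈ 10× but the squared term ≈ 100×.

### Feature selection by the ℓ1,1 projection

$\lVert W_1\rVert_{1,1}$ is the sum over rows (features) of each row's ℓ1
norm. The constraint is enforced by a **two-stage Euclidean projection**:

1. project the vector of row ℓ1 norms onto the ℓ1 ball of radius η, giving
   per-row budgets $t_i \ge 0$ (many exactly zero);
2. project each row onto its own ℓ1 ball of radius $t_i$.

A row with $t_i = 0$ comes out identically zero, so the corresponding
feature is disconnected from the network — selection happens *inside*
training, not as a post-hoc filter. This is deliberately **not** the
Euclidean projection onto $\{W : \sum_{ij} |W_{ij}| \le \eta\}$ (a single
global soft-threshold): that unstructured projection sparsifies individual
weights but leaves most rows alive, selecting weights rather than features.
Both operators are exported (`project_l11()`, `project_l1_matrix()`) so the
contrast can be reproduced; on dense random 200 × 96 matrices at a matched
total norm the structured projection leaves roughly a third as many nonzero
rows.

The per-vector projection uses the exact sort-based algorithm (O(n log n)):
find the soft-threshold θ with $\sum_i \max(|v_i| - \theta, 0) = r$ from the
sorted cumulative sums. The test suite verifies it against an independent
Lagrangian-bisection oracle to 1e-9 on a thousand random vectors. Ties among
equal row norms need no tie-break: soft-thresholding is continuous, so equal
inputs receive equal budgets.

### Double descent

Optimisation is minibatch ADAM (defaults: learning rate 1e-3, batch size 8)
with the projection applied to $W_1$ after every epoch (after every
minibatch via `project_every = "batch"`); budgets are always computed from
the post-ADAM-step weights, the natural projected-gradient ordering. The
loop runs **two descents**: phase 1 trains under the constraint; at the
phase boundary the rows of $W_1$ that the projection has zeroed are frozen
(masked out of all further updates), and phase 2 retrains the surviving
weights — with a fresh optimizer state and the projection still active —
for the same number of epochs. This is the prune-and-retrain scheme with
magnitude thresholding replaced by the ℓ1,1 projection. Within phase 1 the
projection may revive a row it zeroed earlier (that is a property of
projected gradient descent, not a bug); after the phase boundary a pruned
row can never return, which the tests assert.

With `lambda = 0`, `eta = Inf` the decoder and the projection are inert and
the SAE's encoder trajectory coincides *bit for bit* with the plain NN
baseline (`train_nn_baseline()`), because encoder parameters are drawn
before decoder parameters from the seeded stream and each epoch's shuffle is
re-seeded independently. This degenerate-limit equivalence is the package's
strongest internal consistency check: the SAE implementation contains the NN
baseline as a special case rather than as separate code.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `eta` | `Inf` (no selection) | ℓ1,1 budget, in standardized-input weight units; the single knob trading sparsity against fit. Choose with `select_eta()` (CV accuracy, ties to the smallest/sparsest value). |
| `lambda` | 1 | weight of the reconstruction term; 0 recovers a plain classifier. |
| `hidden_width` | 96 | hidden neurons; the reference width for metabolomic tables. |
| `huber_delta` | 1 | residual size (in preprocessed SD units) where the Huber loss turns linear. |
| `epochs` | 30 | per descent phase (total 2 × epochs). |
| `learning_rate`, `batch_size` | 1e-3, 8 | ADAM defaults; batch size is clipped to m. |
| `log_transform` | `FALSE` | apply `log1p` before standardising. **Recommended for raw intensity tables**: LC-MS intensities are approximately log-normal over decades, and training on the raw scale lets a few high-baseline features dominate both losses. |
| `standardize` | `TRUE` | per-feature centring/scaling, fitted on training data only and stored in the model. |

The latent dimension is tied to the number of classes (so the softmax can
read it directly and the latent plot needs no further reduction); an
optional linear head (`linear_head = TRUE`) decouples the two. Biases are
never subject to the constraint — only the d × h weight matrix has feature
rows. Classes are mapped to integers in lexicographic label order, recorded
in the fitted model.

## The evaluation protocol

`cross_validate()` runs the benchmark: stratified 4-fold splits × 3 seeds =
12 train/test evaluations per method, identical splits for every method,
preprocessing fitted inside each training fold only. Stratification is a
package choice (a plain random 4-fold split of an 88-sample cohort can
starve a class); `stratified = FALSE` restores the simpler variant. Fold
assignment is keyed to sample identifiers, so permuting the rows of the
input table does not change who is tested with whom. Metrics are accuracy,
ROC AUC (rank statistic; one-vs-rest mean for k > 2), and the
support-weighted F1 (the "weighted average of precision and recall"
convention appropriate for unbalanced cohorts; `f1_average = "macro"` gives
the unweighted mean). Comparators: PLS-DA with 4 components (arg-max over
the regressed class indicators), random forest with 400 trees of depth ≤ 3
and Gini impurity importance, a linear SVM whose cost C is chosen by an
inner 3-fold grid search over 10⁻³..10³ (smallest C on ties; class scores
from decision values, since Platt scaling is unreliable at small C), and
the NN baseline.

η selection is *not* nested inside every outer fold by default: the package
runs the η grid once on the training data at hand (`select_eta()`), which is
how a single budget per dataset is reported in practice, and because nesting
multiplies training cost by grid × folds at negligible benefit for the
desk-scale problems the package targets. Users who want full nesting can
call `select_eta()` inside their own outer loop.

## What the synthetic generator emulates — and what it does not

`generate_metabolomics()` draws log-intensities from a Gaussian factor
model: per-feature baselines spanning decades of dynamic range, a small
planted set of class-informative features with a standardized mean shift
(`effect_size`, in log-SD units), "adduct/isotope" groups sharing a latent
factor so that within-group Pearson correlation on the **log scale** equals
the configured value, and a fraction of samples contaminated with
heavy-tailed Student-t noise (the outliers that motivate the Huber loss).
Exponentiation makes all intensities positive; note that marginal Pearson
correlations on the raw intensity scale are attenuated relative to the
configured log-scale values, which is why correlation checks in the tests
log-transform first. Presets reproduce the shapes of the three published
clinical cohorts this family of methods is benchmarked on (1005 × 2944,
271 × 161, 88 × 7022) plus a fast 60 × 40 `tiny` preset.

The generator does **not** emulate: retention-time structure, missing values
and detection limits, batch effects, class-dependent covariance, or the
m/z-level chemistry linking adducts to a parent metabolite. Passing tests on
synthetic data therefore demonstrate correctness of the algorithmic
machinery and recoverability under a known ground truth — not clinical
performance on real cohorts, which depends on preprocessing and cohort
effects outside the model.

Test and acceptance problem sizes are a package choice balancing statistical
resolution against feasibility on one CPU: the recovery study uses m = 200,
d = 500 with 10 planted features (effect size 1.5, one adduct group at 0.8)
over 5 seeds; the protocol checks use the `tiny` preset. At these settings
the planted-feature recovery in the top-10 row-norm ranking is ≥ 0.8 and
held-out accuracy ≥ 0.9, both recomputed by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* All arithmetic is 64-bit; constraint checks use absolute tolerance 1e-9,
  idempotence checks 1e-12.
* Weight initialisation is the uniform fan-in scheme
  U(−1/√fan_in, 1/√fan_in), fully seeded; every epoch's batch shuffle is
  seeded from `(seed, epoch)`, so runs are reproducible and
  decoder-independent.
* ReLU's subgradient at exactly 0 is taken as 0.
* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-300.
* `eta = 0` is legal: the first layer becomes all-zero, the classifier can
  still move through its biases, and predictions collapse toward class
  priors. `epochs = 0` returns the (projected) initialisation.
* Constant features receive scale 1 in standardisation rather than dividing
  by zero; the loader flags them.
* A class with fewer members than folds triggers a warned fall-back to
  unstratified folds; a class of size one is rejected by the hold-out
  simulation.

## Interpretation outputs

`rank_features()` reports the row-norm ranking (the direct product of the
constraint: selected set = nonzero rows, exactly) and a gradient × input
attribution of the predicted-class probability as an alternative ordering —
attribution was chosen over sampling-based explanations because it is cheap
and deterministic. `holdout_simulation()` withholds one patient per class,
trains on the remainder and returns confidence scores in [1/k, 1] plus
per-class Gaussian kernel densities along the discriminant latent direction
(bandwidth by Scott's rule via `stats::bw.nrd`); the confidence scores of
any single simulation depend on which patients were withheld and are
illustrative, not population estimates. `feature_correlations()` computes
the Pearson matrix of a selected subset so correlated selections (adduct
groups in real data) are visible at a glance.

## Known limitations

* The encoder has one hidden layer by design; deeper encoders are out of
  scope.
* AUC for k > 2 is a plain one-vs-rest mean; no multiclass calibration is
  attempted.
* The PLS-DA comparator classifies by arg-max of the regressed indicators;
  threshold-based variants exist but are not implemented.
* Training is single-threaded CPU matrix algebra: ample for thousands of
  features and ~10³ samples, not for single-cell-scale data.
* Confidence is the maximum softmax probability — a useful triage signal,
  not a calibrated posterior; miscalibration on shifted cohorts is exactly
  why the latent-space plot accompanies every prediction.
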