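# saefs — sparse supervised autoencoders for clinical metabolomics

`saefs` classifies samples-by-features metabolomic intensity tables (LC-MS or
GC-MS feature matrices with columns like `MZ 264.12`) with a **supervised
autoencoder** whose first encoder layer is constrained to an ℓ1,1 ball, so
that training simultaneously learns a classifier and performs embedded
feature selection. It is aimed at researchers building diagnostic or
prognostic models from omics feature tables who need three things classical
classifiers do not give together: a per-patient **confidence score**, a
**two-dimensional latent space** in which each patient can be placed among
the training cohort, and a short, biologically inspectable list of
**selected features**.

## The model

Let `X` be the m × d data matrix and `y_i ∈ {1..k}` the class labels. The
network is an encoder `d → 96 (ReLU) → k`, a mirrored decoder
`k → 96 (ReLU) → d`, and a softmax head applied directly to the latent code
`Z` (the latent dimension equals the number of classes). Training minimises

```
Loss(W) = φ(Z, Y) + λ ψ(X̂ − X)     s.t.   ‖W₁‖₁,₁ ≤ η
```

where `φ` is the softmax cross-entropy in the latent space, `ψ` the Huber
(smooth ℓ1) reconstruction loss — robust to outlier samples; a squared-error
variant is available — and `‖W₁‖₁,₁ = Σᵢ ‖row_i(W₁)‖₁` is the row-structured
sparsity norm of the first encoder layer. The constraint is enforced by a
two-stage projection: per-row ℓ1 budgets `tᵢ` are obtained by projecting the
vector of row norms onto the ℓ1 ball of radius η, then each row is projected
onto its own ball of radius `tᵢ`. Rows with `tᵢ = 0` are exactly zero: whole
features are deselected, unlike a plain ℓ1 projection which only zeroes
individual weights. Optimisation uses minibatch ADAM in a **double-descent**
loop: a constrained first pass, then pruning of the zeroed feature rows and
retraining of the survivors with the projection still active.

η is chosen by cross-validated accuracy (`select_eta()`), and models are
benchmarked against PLS-DA (4 components), random forests (400 trees, depth
≤ 3), a linear SVM with inner-CV grid search over C, and a plain neural
network of the same architecture, under a stratified 4-fold × 3-seed
cross-validation protocol (12 train/test splits per method; accuracy, AUC
and support-weighted F1).

## Worked example

Everything runs on synthetic LC-MS-like data with planted ground truth, so
the example is fully reproducible:

```r
library(saefs)

sim <- generate_metabolomics(synthetic_preset("tiny", seed = 1))
fit <- train_sae(sim, config = sae_config(eta = 10, log_transform = TRUE, seed = 1))
fit
#> <supervised autoencoder> 40 features -> 96 hidden -> 2 latent, 2 classes
#>   trained on 60 samples, 30 epochs x 2 phases
#>   l1,1 budget 10; 7 / 40 feature rows selected
```

Of 40 features, the ℓ1,1 constraint kept 7. The row-norm ranking recovers
the planted informative features (`MZ 379.93`, `MZ 118.08`, `MZ 837.73`, ...
are all members of `attr(sim, "informative_features")`):

```r
head(rank_features(fit), 5)
#>   feature   score  rank method   selected
#> 1 MZ 379.93  2.08     1 row_norm TRUE
#> 2 MZ 118.08  1.93     2 row_norm TRUE
#> 3 MZ 837.73  1.74     3 row_norm TRUE
#> 4 MZ 161.47  1.51     4 row_norm TRUE
#> 5 MZ 992.39  1.33     5 row_norm TRUE
```

The clinical-deployment simulation withholds one patient per class, trains
on the rest, and reports each "new patient" with a softmax confidence score
and latent coordinates (`autoplot()` draws them among the training cloud):

```r
holdout_simulation(sim, config = sae_config(eta = 10, log_transform = TRUE, seed = 1))
#> <sae_holdout> 2 held-out samples
#>   .sample    .true_class .pred_class .confidence
#> 1 sample_052 class_0     class_0           0.997
#> 2 sample_005 class_1     class_1           0.981
```

Both withheld patients are classified correctly, with confidence 0.997 and
0.981 (1/k = 0.5 would be an uninformative prediction). Finally, the
benchmark protocol compares methods on identical splits:

```r
cv <- cross_validate(sim, config = sae_config(eta = 10, log_transform = TRUE),
                     methods = c("sae_huber", "plsda", "rf"))
glance(cv)
#>   method    n_splits accuracy   auc    f1
#> 1 plsda           12    0.900 0.968 0.900
#> 2 rf              12    0.955 0.997 0.955
#> 3 sae_huber       12    0.967 1     0.966
```

A thin command-line wrapper with `simulate`, `train`, `select-eta`,
`benchmark`, `holdout-sim` and `rank-features` subcommands is installed at
`system.file("cli/saefs.R", package = "saefs")`.

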