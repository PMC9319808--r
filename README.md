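# histobias

Histopathology patch classifiers are notorious for learning the wrong
thing: scanner and stain regimes, skewed sampling ratios, missing tissue
types, or artifacts that happen to correlate with the diagnosis. When
that happens the test metrics can look excellent while the decision
logic is clinically meaningless. `histobias` is a validation pipeline
for *bias discovery*: it plants known biases into synthetic
histology-like data, trains a compact CNN on them, and checks that two
explanation methods — automated concept extraction scored with concept
activation vectors (TCAV), and Guided Grad-CAM saliency maps — recover
each planted bias from the trained model alone.

The package is aimed at researchers building or auditing explanation
tooling for computational pathology who want a fully controlled, fully
reproducible test bed: every bias is planted by construction and every
recovery check is scored against the generator's ground truth.

## What is inside

**Synthetic tile generator** (`generate_tile()`, `build_dataset()`).
Two-class "cancerous vs non-cancerous" tiles: pink stroma, dark nuclei
whose density/size carry the class signal, optional collagen bands and
background regions, two acquisition sources that differ by a global
brightness/contrast regime, and virtual slides for slide-disjoint
train/validation/test splits (66.67/16.67/16.67%). Four bias-injection
procedures: class sampling ratio (positives rejected from the training
pool with probability 0.5, giving a ~2:1 imbalance), measurement bias
(label perfectly confounded with source), sampling bias (a tissue
stratum excluded from training negatives), and class-correlated bias (a
small red square planted in the upper-left corner of every positive
tile).

**CNN** (`build_model()`, `train_cnn()`, `evaluate_cnn()`). A small
residual network: 7x7/32 stride-2 stem, 3x3/2 max pool, residual stages
of widths 32 and 64 (stride-2 projection shortcut into the second
stage), global max pooling, a 16-unit fully connected layer and a
2-class softmax, Swish activations throughout. Trained from scratch with
Adam (learning rate 2e-4, batch size 32), inverse-frequency class
weights, L2 penalty, checkpointing and early stopping on validation
loss, and augmentation: random flips, full-circle rotation, optional HSV
jitter, and random cutout filled with grey 127. The forward/backward
engine is written in Rcpp/Armadillo and exposes named layer activations
and class-logit gradients for the explanation modules.

**Concept extraction + TCAV** (`ace_extract()`, `run_tcav()`).
Multi-resolution SLIC-zero superpixels (15/50/80 segments at 256 px,
scaled by area at smaller tile sizes) are rendered on grey-127 canvases
at their original location and scale, embedded at the FC layer,
clustered with k-means (k-means++ seeding), and filtered (top-40 patches
per cluster, minimum membership and tile spread). Each concept's CAV is
the oriented unit normal of a linear SVM separating concept from random
counterexample embeddings; TCAVQ for class k is the fraction of class-k
inputs whose class-logit gradient has positive dot product with the CAV.
Over repeated runs (fresh counterexamples each run) scores are tested
against random-vs-random null CAVs with a two-sided Welch t-test at
alpha = 0.01.

**Saliency** (`compute_heatmap()`, `render_heatmap()`). Grad-CAM on the
deepest spatial layer (gradient-weighted, ReLU-rectified feature-map
sum), guided backpropagation with the gating rule applied at Swish
sites, and their pointwise product, rendered as tile / overlay / guided
triptychs.

**Experiments and bias flags** (`run_experiment()`,
`summarize_experiments()`). Five study configurations (`feature_vis`,
`class_ratio`, `measurement`, `sampling`, `class_correlated`) with
biased/unbiased model pairs where defined, and operational decision
checks: a *dominance shift* (the majority of significant concepts vote
for the absence-defined negative class), *marker overlap* (a significant
positive concept whose patches hit the planted marker), and *source
purity* (a significant concept drawn entirely from one source).

## Worked example

Train a model on the class-correlated dataset and ask the explanations
whether it cheats:

```r
library(histobias)

ds  <- build_dataset(bias_config("class_correlated"),
                     n_slides = 12, tiles_per_slide = 12, seed = 11)
fit <- train_cnn(build_model(96, seed = 1), ds,
                 epochs = 40, patience = 10, seed = 2)
evaluate_cnn(fit, ds$test)
#> <cnn_metrics n=24  bacc 1.000  auc 1.000  f1 1.000  precision 1.000  recall 1.000>

con <- ace_extract(fit, ds$test, k = 5, seed = 3, max_tiles = 24)
res <- run_tcav(fit, con, ds$test, runs = 20, seed = 4)
tidy(res)[5:6, ]
#> # A tibble: 2 x 7
#>   concept_id class     mean   std  p_value significant  runs
#>        <dbl> <chr>    <dbl> <dbl>    <dbl> <lgl>       <dbl>
#> 1          3 positive     1     0 0.000119 TRUE           20
#> 2          3 negative     0     0 0.000119 TRUE           20

marker_overlap_check(con)[3, ]
#> # A tibble: 1 x 2
#>   concept_id overlap
#>        <dbl>   <dbl>
#> 1          3     0.9
```

The model reaches perfect test metrics — and the explanation shows why:
concept 3's patches overlap the planted red square in 90% of cases and
the concept drives the positive class in every one of 20 CAV runs
(mean TCAVQ 1.0, sd 0.0). A
reader without ground truth would see a gallery of red-cornered patches
(`write_concept_gallery()`) and a bar chart with an asterisk on the
marker concept (`autoplot(res)`); Grad-CAM (`compute_heatmap()`)
concentrates on the same corner. The marker, not the tissue, is the
decision rule.

On the number of concepts `k`: duplicate-looking concepts suggest
decreasing `k`, mixed/incoherent concepts suggest increasing it; there
is no automatic choice.

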