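---
title: "Validating concept-based and saliency explanations for bias discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating concept-based and saliency explanations for bias discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

A histopathology patch classifier can reach excellent test metrics for
the wrong reasons: it may key on scanner or stain characteristics that
happen to be confounded with the diagnosis, on artifacts correlated
with one class, or its decision logic may be distorted by skewed or
selective sampling of the training data. Explanation methods are
supposed to surface such defects, but the claim that they *do* needs
validation. The approach here is constructive: plant a known bias into
synthetic data, train a model, and check — against the generator's
ground truth — that the explanations recover the plant.

Two explanation families are implemented. *Concept-based*: superpixel
segments of evaluation tiles are embedded in the network's activation
space, clustered into concepts, and each concept's class influence is
quantified with concept activation vectors (TCAV). *Saliency-based*:
Grad-CAM localization maps sharpened by guided backpropagation.

## The synthetic data and what it does (not) emulate

A tile is a pink stroma texture with dark, softly-edged elliptical
nuclei; the positive ("cancerous") class has denser and slightly larger
nuclei than the negative class. Tiles belong to virtual slides; a slide
contributes a deterministic cellularity multiplier (log-normal,
sd 0.35) and a small stain-tone shift, so that slides — not just tiles
— differ, and splits are made slide-disjoint exactly as one must do
with real whole-slide images. Two acquisition sources A and B stand for
two scanner/stain regimes; B tiles pass through a fixed per-channel
affine map (contraction 0.7 toward reference channel means, then a
brightness factor 1.12) that makes them brighter with less color
variation. Optional strata add a wavy collagen band (standing for
reticular dermis) or a near-white background region; tiles are
re-rendered if near-white pixels (all channels >= 240) would exceed
10%.

The class separation is deliberately imperfect: nucleus densities 26
vs 18 per 96 px tile and radii 3.1 vs 2.7 px overlap within and across
slides. A tissue-only model therefore scores well but not perfectly,
while every planted confound (a source shift or a marker present on
100% of positive tiles) is a *perfect* signal. This mirrors the
structure that makes bias discovery necessary in practice: the shortcut
is easier than the biology, so the model takes it, and the test metrics
saturate without the model having learned anything about tissue. Under
an earlier, more separable calibration the trained network preferred
the nucleus signal and largely ignored the marker; the overlapping
calibration was fixed in that light and then left alone.

What the generator does *not* emulate: real nuclear morphology and
chromatin texture, stain deconvolution physics, spatial tissue
architecture, label noise, or scale variation across magnifications.
Passing these tests therefore shows that the explanation pipeline is
*sound* — it recovers the signal the model actually uses — not that it
will surface every bias in real dermatopathology data.

## The classifier

The network is a small residual CNN: a 7x7, 32-filter, stride-2 stem; a
3x3 stride-2 max pool; two residual blocks of two 3x3x32 convolutions;
three residual blocks of two 3x3x64 convolutions with the first
downsampling by stride 2 (1x1 projection shortcut); global max pooling;
a 16-unit fully connected layer; a 2-class softmax. Swish is used at
every activation site because ReLU's dead units would zero gradients
that the explanation methods need. At 256 px input the stage outputs
are 128, 64 and 32 px; the default working size is 96 px (12 px deep
feature maps), and because the body is fully convolutional the
parameter count is identical at any input size.

Training follows a fixed protocol: pixels scaled to [0, 1], Adam with
learning rate 2e-4 and batch size 32, inverse-frequency class weights,
L2 weight penalty 1e-4 (the coefficient is a conventional magnitude,
config-exposed), per-epoch shuffling, checkpointing of the best
validation loss, and early stopping with configurable patience. The
class-sampling-ratio experiment deliberately drops early stopping and
class weights and runs a fixed epoch budget, since rescuing the model
from the imbalance would mask the bias under study. Augmentation:
horizontal flip (p = 0.5), rotation by a uniform angle in [0, 360)
(bilinear with reflective borders, so no empty corners are introduced),
optional HSV jitter (hue +-0.05, saturation/value +-20%) used in the
two-source feature-visualization setting, and random cutout (p = 0.5,
side 10-40% of the tile) filled with grey 127.

The cutout fill value matters more than it looks: concept patches are
rendered on grey-127 canvases, and a network never exposed to grey
regions treats the segment *shape* as a feature and drifts toward
arbitrary class votes on patch canvases. Training with grey-127 cutout
makes grey areas class-neutral, which is a precondition for meaningful
concept scores; the pipeline therefore keeps cutout on by default.

## Concept extraction

Segments come from SLIC-zero (adaptive compactness) at three
resolutions — 15/50/80 segments at 256 px, scaled by `(size/256)^2`
(minimum 4) so segment *area* is preserved at smaller tile sizes.
Segments below 0.5% of the tile area are dropped. Each segment is kept
at its original location and scale on a grey-127 canvas: cell size is
informative in histology, so patches are not normalized; and location
must not be informative, which is why embeddings are taken at the fully
connected layer after global pooling rather than at a convolutional
layer — convolutional feature maps are spatially arranged and make the
clustering group patches by position rather than content (kept as a
regression test). Embeddings are clustered with k-means (k-means++
seeding, fixed seed); per cluster the 40 members nearest the center
(ties broken by patch index) form the concept, and clusters with fewer
than 20 members or drawn from fewer than 5 distinct tiles are
discarded. These two thresholds are declared defaults standing in for
the published filtering heuristics, which do not fix numbers. The
cluster count k is set per experiment (default 5): duplicate concepts
indicate k is too high, mixed concepts that it is too low; automatic
selection is out of scope.

## TCAV

For a concept C and class k at layer l, a linear SVM (C = 1) separates
concept embeddings from 40 random counterexample segments drawn fresh
each run from the pooled SLIC segments of the evaluation tiles; the CAV
is the unit normal oriented toward the concept side. Embeddings are
conditioned by one global scalar (the standard deviation of the
combined matrix) before fitting: raw activations are large enough that
C = 1 would act as a hard margin, and the handful of concept-like
segments that inevitably land in a random draw would then rotate the
boundary; a scalar factor restores a calibrated soft margin without
reweighting the embedding geometry, which per-dimension standardization
would do. The sensitivity of input x is the dot product of the CAV
with the gradient, with respect to the layer-l activations, of the
quantity that maximizes the class-k prediction; in a 2-class softmax
that is the logit margin (logit_k minus the other logit), since any
common-mode component shared by the two logits cancels in the
prediction and would only inject sign noise into the directional
derivative. (`class_gradient()` exposes both the raw-logit and the
margin target; TCAV uses the margin, and under it the two classes'
scores are exact complements.) TCAVQ is the fraction of class-k
evaluation inputs with strictly positive sensitivity (zeros count as
non-positive). With the FC layer as l and a linear head above it, that
gradient is input-independent, so each run's score is saturated at 0 or
1 and the interesting variation is across runs — which is precisely
what the repeated-run protocol measures. Per run a random-vs-random CAV
is scored on the same inputs as the null; concept scores are compared
to null scores with a two-sided Welch t-test, significant at
alpha = 0.01, with no multiple-testing correction across concept-class
pairs (each concept is tested at its own alpha; noted in the output
metadata). Evaluation inputs are the test split's class-k tiles, capped
at 100. The full protocol uses 100 runs; the working configuration uses
20, which widens the standard-deviation estimate but leaves saturated
concepts (mean 1.0, sd 0.0) unaffected.

Degenerate situations are handled explicitly: identical concept and
random sets refuse to produce a CAV; constant score vectors on both
sides yield p = 1 (equal means) or p = 0 (different means); fewer than
two runs yield no p-value and no significance claim.

## Saliency

Grad-CAM weights each deepest-layer feature map by the spatial mean of
the class-score gradient and rectifies the weighted sum; the target
layer is the last convolution of the 64-channel stage (the deepest
spatial layer). The target score is the class margin (logit_k minus the
other logit), for the same reason as in TCAV: through a global-max-pool
head the raw logit's gradient is spatially sparse and carries a large
common-mode component shared by both classes, and maps built from it
fail to localize even a planted, perfectly class-aligned feature; the
margin cancels the common mode (the raw-logit target remains available
via `target = "logit"`). Guided
backpropagation applies the published gating rule — zero the backward
signal where the incoming gradient or the forward pre-activation is
negative — at every Swish site, using the pre-activation sign; how the
original formulation should transfer from ReLU to Swish is genuinely
open, and this choice preserves the rule's intent while `gates = FALSE`
recovers the exact input gradient (verified against finite
differences). Guided Grad-CAM is the pointwise product of the
bilinearly upsampled coarse map with the guided image; quantitative
checks use the coarse map and the product's channel magnitude, signed
RGB is kept for display.

## Bias flags

The study's judgements about explanation output are operationalized as
three checks with declared, config-exposed thresholds: *dominance
shift* — among significant concepts (mean TCAVQ > 0.5 for their class),
the negative class holds the majority; flagged because a class defined
by the absence of disease features should not own the decision
criteria. *Marker overlap* — a significant positive-class concept whose
patches intersect the marker region (generator ground truth) in >= 90%
of cases. *Source purity* — a significant concept whose patches all
come from one source. The thresholds (0.5 / 0.9 / 1.0) are proxies for
what was originally a human reading of concept galleries and bar
charts.

## Problem sizes and numerical choices

Three presets are used throughout. `paper` restores the full-fidelity
configuration (256 px tiles, up to 100 epochs, 100 TCAV runs). `desk`
is the default working scale — 96 px tiles, 30 slides x 40 tiles,
20 TCAV runs — chosen so that a complete confound study trains in a few
minutes on one CPU core; the acceptance script runs at this scale with
short epoch budgets (5 for the measurement confound, which saturates in
2 epochs; 12 for the marker). `mini` (12 slides x 12 tiles) is the
package's own test-suite scale; the saturation phenomena are
scale-robust, and the direction-only checks (class-ratio AUC ordering,
sampling-bias dominance shift) are asserted across five seeds rather
than as magnitudes because mid-range metric values depend strongly on
test-set size. The marker configuration gets a longer epoch budget than
the measurement configuration at every scale: a global appearance shift
is visible to the stem's first filters, while an 8 px corner square
under rotation augmentation needs more optimization steps before the
network discovers it.

Numerical conventions: coordinates are row-major, origin top-left,
0-based half-open in all geometry specifications (R's 1-based indexing
is translated at the boundary); near-white means all channels >= 240;
k-means ties and global-max-pool argmax ties break to the first index;
AUC is the trapezoidal ROC area (rank formulation, ties counted half);
sample standard deviations are reported. Seeds fan out from one master
seed through a fixed integer-mixing function, so every stage (dataset,
initialization, shuffling, concept seeding, per-run counterexample
draws) is independently reproducible; identical configuration and seed
reproduce datasets byte-for-byte, while training metrics are
reproducible to floating-point noise.

A caveat on saturated balanced accuracy at the working scale: the
confounded models always reach AUC 1.0 on the held-out slides (the
planted signal ranks every positive above every negative), but the
argmax threshold can drift on individual held-out slides whose
appearance differs from the training slides, so balanced accuracy
occasionally reads a few points below 100% with only 5 test slides.
This is a calibration artifact of the small virtual-slide count, not a
failure to learn the planted bias; the full-fidelity configuration with
its larger effective diversity does not show it.

## Known limitations

The FC-layer gradient degeneracy discussed above means per-run TCAVQ
values are 0/1-saturated in this architecture; distributional spread
comes from CAV resampling only. The SVM cost parameter and the
filtering thresholds are declared rather than derived. The generator's
realism limits are listed above; in particular, concepts extracted here
(nuclei blobs, collagen bands, a red square) are far simpler than real
histopathological concepts, so these tests bound the pipeline's
correctness, not its clinical interpretability. Location-dependent
biases are out of scope by design: concept patches carry no location
context, so a bias tied to, say, the patch center is invisible to the
concept pipeline and is the province of the saliency maps.
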