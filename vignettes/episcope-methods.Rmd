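---
title: "Epidermis-centric analysis of skin histology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epidermis-centric analysis of skin histology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`episcope` analyses H&E-stained skin histology images around the structure
that carries most of their diagnostic signal: the epidermis and the
basement-membrane zone (BMZ), the junctional region where the epidermis
meets the dermis. The pipeline runs in stages, each usable on its own:

1. **Stain normalization** standardizes slide colours (Macenko method).
2. **Epidermis segmentation** finds the epidermis band without any
   annotation, by self-training a small CNN against its own
   superpixel-refined predictions.
3. **Hierarchical patch sampling** extracts 512×512 "level-2" patches
   along the epidermis and 128×128 "level-3" patches along the
   epidermis–dermis boundary, so every patch contains the same anatomy
   (dermis, BMZ, epidermis, corneum) in the same diagonal orientation.
4. **Morphometrics** quantify epidermal thickness and rete-ridge
   prominence from the two epidermis boundaries.
5. **Radiomics** extract a fixed 106-feature vector per patch and rank
   features with a random forest.
6. **A CNN classifier** is trained and evaluated under slide-level
   cross-validation, and **Grad-CAM** traces which image regions drive its
   decisions.

A synthetic skin-tissue generator with exact ground truth makes every
stage testable without any external slides.

## The synthetic generator and what it does (and does not) emulate

`generate_sample()` builds a three-layer tissue: a pale stratum corneum on
top, an epidermis band, and dermis below. The epidermis–corneum boundary
("ES") is flat; the epidermis–dermis boundary ("EB") is a sinusoid

\[ y(x) = t_c + t_e + A \sin(2\pi x / \lambda), \]

where \(t_c\) is the corneum thickness, \(t_e\) the mean epidermal
thickness, \(A\) the ridge amplitude and \(\lambda\) the wavelength (all in
pixels). The sinusoid mimics rete ridges — the undulations of the
epidermis into the dermis that flatten with age. Nuclei are dark,
non-overlapping ellipses (4–8 px axes, rejection-sampled with at most 100
placement attempts each) drawn only inside the epidermis; they give texture
features something real to measure without simulating chromatin. Additive
Gaussian noise (clipped to 0–255) is the stationary noise model, and an
optional rotation of the whole stack (nearest-neighbour for the mask,
reflective padding, polylines rotated analytically) keeps the ground truth
exact under reorientation.

The mask is pixel-exact by construction: a pixel at row \(r\) is epidermis
iff \(t_c + 0.5 < r < y(x) + 0.5\), and the returned boundary polylines are
the same continuous curves that rasterization used. One consequence worth
knowing: boundary statistics recovered *from the mask* carry a ≈1 px
pixel-grid bias (a 30 px band's two pixel edges are 29 px apart), which is
why thickness recovery is asserted at 5% rather than exactly.

`generate_cohort()` draws labelled "young" (thick, ridged) and "aged"
(thin, flat) groups, jittering each sample's thickness and amplitude around
the group means with a 10% relative standard deviation — enough spread to
be realistic, little enough that the groups stay separable, mirroring the
morphometric differences reported between young and aged skin.

What the generator does **not** emulate: real chromatin and cytoplasm
texture, hair follicles, glands and vessels (a simple dermal distractor-blob
option stands in for them), stain variability across slides, scanner
artefacts, and gigapixel scale. Tests passing on synthetic data therefore
demonstrate algorithmic correctness — not clinical performance.

## Stain normalization

Colours are handled in optical density, \(\mathrm{OD} = -\log_{10}((I +
1)/256)\); the +1 avoids \(\log 0\). Pixels with any channel below the
transparency threshold β = 0.15 OD are background. The OD cloud of tissue
pixels is projected onto its two largest-variance directions; the
directions at the 1st/99th percentile of the projected angle (α = 1) are
the two stain vectors, ordered hematoxylin-first by blue-channel OD.
Concentrations are solved by least squares with negatives clipped at zero
(a config switch enables the exact two-variable non-negative solve), scaled
by the ratio of reference to source 99th-percentile maxima, and re-rendered
through the reference stain matrix. Background pixels pass through
untouched so white regions never acquire a stain tint. β and α are the
canonical defaults of the method; the reference stain model is an explicit
required input since no single cohort-wide reference is canonical.

## Unsupervised epidermis segmentation

Felzenszwalb graph-based superpixels (implemented in C++ in this package;
edge weight = RGB distance after Gaussian smoothing) group similar pixels.
A small CNN — blocks of 3×3 convolution, ReLU and per-image normalization,
ending in a 1×1 convolution and softmax — is then trained *on the image
itself*: each iteration, the per-pixel argmax labels are replaced by the
majority label within each superpixel, and the cross-entropy between the
scores and these refined labels is backpropagated (SGD with momentum 0.9).
The loop stops when the number of distinct labels reaches `min_clusters`
(3: corneum / epidermis / dermis) or at `max_iterations`. A normalization
layer after the 1×1 head keeps the class logits comparable, which is what
prevents the clustering from collapsing into one class in the first few
iterations.

Two genuinely open design points and the choices made:

* **Which cluster is the epidermis?** The clustering is unsupervised and
  does not name its clusters. The default heuristic scores each cluster by
  mean hematoxylin-like OD × elongation of its largest connected component
  — the epidermis is the nucleus-dense, band-shaped cluster — with clusters
  under 2% of the image ineligible (thin boundary slivers can otherwise win
  on elongation alone). Ties break toward the smaller cluster id, and an
  explicit `cluster_id` overrides the heuristic. This rule is this
  package's own; treat it as a default to be checked on new data.
* **Filtering non-epidermis structures.** Masks dominated by follicles,
  glands or vessels are removed solely by the diagonal-span criterion: a
  connected component must touch both corner regions (squares of side
  0.15·min(H, W)) of either image diagonal. Before the test,
  `extract_level1()` recenters the mask centroid and, when the principal
  axis deviates more than 20° from a diagonal, rotates the stack — so the
  criterion judges shape, not position. No other filters are applied.

"Corrosion–expansion" cleanup is implemented as morphological opening
(disk radius 3) followed by removal of components under 256 px.

Default capacity is 100 feature channels and 3 conv blocks with up to 100
iterations. The test suite and the bundled experiments run a reduced
configuration (10 channels, 1 block, 60 iterations, 96×96 images) chosen
for CPU speed; on the synthetic three-band images it converges to 3
clusters in well under 60 iterations with mean epidermis IoU ≈ 0.97.

## Patch sampling

Level-2 centers are placed every `stride2` arc-length pixels along the
skeleton path of the epidermis mask (Zhang–Suen thinning, then the longest
path through the 8-connected skeleton graph, oriented to start at the
lexicographically smaller endpoint). Level-3 centers walk the EB-side
boundary of the mask — the dermis-adjoining side, i.e. the BMZ — inside a
level-2 patch. Crops are half-open `[r, r+size) × [c, c+size)`, 0-based;
centers too close to a border are shifted inward to the nearest valid
position (never padded: padding would fabricate tissue and corrupt
radiomics), off-mask centers snap to the nearest mask pixel, and duplicates
are dropped order-preservingly. Strides default to the patch size
(non-overlapping); overlap is a config choice.

The BMZ inclusion filter keeps a level-2 patch iff its epidermis fraction
lies in [0.1, 0.9] (both epidermis and non-epidermis tissue present) and
the mask's principal axis is within 25° of a patch diagonal.

## Morphometrics

With EB and ES the epidermis–dermis and epidermis–corneum boundaries,

* thickness \(= \operatorname{mean}_i d(\mathrm{ES}_i, \mathrm{EB})\) (pixels),
* rete ridge score \(= \operatorname{var}_j d(\mathrm{EB}_j, \mathrm{ES})\) (pixels²),

where \(d\) is the shortest point-to-polyline distance (point-to-segment,
not point-to-vertex). The definition is asymmetric on purpose: ES→EB
distances vary with the ridges and average to the thickness, while EB→ES
distances vary *because of* the ridges, so their variance measures ridge
prominence. A flat junction scores 0; larger amplitude scores higher. The
variance uses divisor \(n\) (population form); with boundaries resampled at
1-px arc steps, \(n\) is large and the choice is immaterial, but it is
fixed for reproducibility. How the index sets are sampled is not canonical;
uniform arc-length resampling is this package's convention.

Boundary extraction splits the mask's outer contour at the skeleton
endpoints, trims half a band-width around each endpoint (removing the short
end caps), and assigns roles by the stain rule — the side whose 10-px outer
band is more hematoxylin-dense is EB — falling back to "the more undulating
side is EB" when no image is supplied. Masks whose skeleton endpoints are
closer than \(\sqrt{\text{area}}\) (disk-like topology) are rejected with a
topology error rather than guessed at.

## Radiomics

Each patch yields exactly 106 named features in a pinned order: 18
first-order intensity statistics, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and
14 GLDM texture features, plus 13 image/mask diagnostics. Texture matrices
are computed on the luminance channel (0.299 R + 0.587 G + 0.114 B — the
one documented channel convention), discretized at a fixed bin width of 25
intensity units, at distance 1 with the four 2-D directions merged
symmetrically; size zones use 8-connectivity. NaN-producing degenerate
cases (e.g. skewness of a constant patch) become 0 and are flagged, keeping
vectors rectangular for the forest. Features default to the full patch;
a mask-restricted mode is available since either convention is defensible.

The published description of this feature set gives 106 in one place and
101 in another; the schema here standardizes on 106 and pins it in
`radiomic_feature_manifest()` — extraction fails loudly rather than drift.

The random-forest ranking (500 trees, impurity importance normalized to
sum 1, fixed seed, single-threaded for determinism) reports the top 5
features. One practical caveat the tests encode: when two groups differ by
a pure intensity shift, that signal is shared by ~14 perfectly correlated
location features (mean, median, percentiles, RMS, the diagnostics means),
so importance spreads among them and *which* of them lands in the top 5 is
seed-dependent; the family as a whole dominates robustly. Cross-validated
evaluation groups patches by slide (`wsi_id`) so no slide straddles a
train/test split.

## CNN classification and evaluation

The training protocol is SGD with learning rate 0.01 and mini-batch size 1
(gradient accumulation implements larger batches when configured). Folds
are stratified slide-level partitions: every patch inherits its slide's
fold, and an explicit leakage guard fails evaluation if a test slide ever
appears in its fold's training set. Metrics: accuracy, ROC-AUC by
trapezoidal integration with tied scores grouped, PR-AUC by the step-wise
precision envelope, and macro-F1; multi-class AUCs are macro one-vs-rest.
Patch-level predictions are the unit of evaluation, with optional
slide-level aggregation by mean class score.

The package has no deep-learning framework dependency: it carries a
compact CNN engine (BLAS-backed im2col convolutions with hand-written
backward passes, validated against finite differences in the test suite).
Two backbones are provided: `small_cnn` (three conv/pool blocks and a
linear head), the first-class CPU backbone used throughout the tests, and
`resnet_small`, a residual-block variant in the ResNet style. Pretrained
weights are not distributed, so `pretrained = TRUE` warns and uses random
initialization; normalization layers run in per-image (instance) mode at
both train and test time, which makes inference deterministic and
batch-free. Epoch count is not canonical; the default is 10, and the
bundled experiments use 4 epochs at 48×48 input resolution, which separates
the synthetic cohorts with pooled out-of-fold accuracy ≥ 0.95.

## Grad-CAM hotspot tracing

For a target class, channel weights are the spatial means of the gradient
of the class score at a chosen convolutional layer; the heatmap is the ReLU
of the weighted channel sum, min-max normalized (an all-zero raw map maps
to all zeros rather than dividing by zero) and bilinearly upsampled to the
patch. Two deliberate options where conventions diverge:

* **Tap point.** The default is the last convolutional layer — the
  established Grad-CAM convention, semantically the most meaningful — with
  `"first_conv"` available, since heatmaps are sometimes described at the
  first layer's resolution; both are exposed rather than asserting one
  reading.
* **Gradient source.** The pre-softmax class logit by default (invariant to
  positive logit rescaling), with a cross-entropy-loss mode as an option.

On the synthetic young-versus-aged classifier, heatmaps for the "aged"
class concentrate inside the epidermis mask: the inside/outside mean-heat
ratio exceeds 1 for ≈90–100% of out-of-fold patches — the package-level
restatement that the epidermis and BMZ carry the discriminative signal.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 1-based in R code; crops half-open as above.
* All randomness flows from explicit integer seeds (Mersenne–Twister,
  inversion normals); same seed ⇒ bit-identical outputs, including the C++
  superpixel stage (stable sort) and the forest (fixed seed, one thread).
* Ties: cluster selection and fold argmax take the first maximum (lowest
  index); superpixel majority votes break toward the smaller label.
* Degenerate inputs fail with typed messages rather than propagating NaN:
  near-blank images (stain estimation), single-stain OD clouds, single
  clusters (no-epidermis), disk-topology masks, empty regions in
  mask-restricted radiomics, single-class labels in the forest.
* Problem sizes in the tests (96×96 segmentation images, 320×320 cohort
  "slides", 160-px level-2 patches downscaled to 48×48 for the CNN, 10–20
  samples per experiment) are the package's chosen fixture scale: large
  enough that every property is exercised at meaningful statistical
  resolution, small enough to run quickly on one CPU.

## Known limitations

* The epidermis-cluster heuristic and the diagonal-span filter encode
  assumptions (nucleus-dense elongated band; diagonal orientation) that
  hold for skin sections but not arbitrary tissue.
* Radiomic values follow standard formula families but are not
  numerically certified against any external extractor; the schema, not
  cross-tool equality, is the contract.
* The CNN engine is single-image and CPU-bound by design; it is not a
  substitute for a GPU training stack at clinical scale.
* Synthetic validation bounds what passing tests can claim about real
  slides (see the generator section).
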