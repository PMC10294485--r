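---
title: "Weakly-supervised whole-slide classification across centers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised whole-slide classification across centers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Histology archives label slides, not pixels. A whole-slide image (WSI) of a
pancreatic resection is "tumor" or "control" as a whole, even though much of
a tumor slide is ordinary tissue. `wsimil` implements the standard
weakly-supervised answer — multiple-instance learning (MIL) — together with
everything a multi-center study wraps around it: tiling and tissue masking,
stain normalization, patient-level aggregation, patient-wise
cross-validation, cross-dataset protocols, and a quantitative batch-effect
diagnosis.

The package's second concern is the failure mode of dataset integration.
When one source contributes (almost) only tumor slides and another only
controls, the class label is confounded with the dataset of origin, and a
classifier can "succeed" by recognizing the source — its staining and
scanning fingerprint — rather than the biology. The package ships a
synthetic-cohort generator that reproduces exactly this structure, so the
phenomenon and its mitigation can be demonstrated and tested end to end on
a desk machine, with no access to controlled archives.

# Pipeline and model

## Tiling

A slide is converted to luma grayscale and thresholded with Otsu's method
(the exhaustive-equivalent 256-bin between-class-variance argmax; pixels
darker than the threshold are tissue, because H&E tissue is darker than the
near-white scanner background). A non-overlapping 256×256 grid anchored at
the origin is then filtered: a tile is discarded if strictly more than 60%
of its footprint is background, or if its grayscale standard deviation is
below 8 (on the 0–255 scale). At most 4000 tiles are kept per slide; when
more survive, a uniform random subsample is drawn on the sorted tile
identifiers, which makes the kept set independent of traversal order.

Two of these rules are not uniquely determined by common practice and were
fixed as package decisions: the low-contrast cutoff (sd < 8 rejects blank
and blurred tiles without touching textured tissue) and the over-cap
selection rule (uniform, seeded per slide). Exactly 60% background is kept
— the discard condition is a strict inequality. Tile stores are written as
validated array containers (the `tiles` array plus parallel statistic
arrays and scalar attributes) with lossless round trips.

## Stain normalization

Reinhard color transfer operates in Ruderman's lαβ space: RGB is linearized
to 0–1, projected onto LMS cone responses, log-transformed (log(1+x), so
zeros are safe), and decorrelated by a fixed orthogonal opponent transform.
Normalization is a single affine moment transfer per channel — subtract the
tile's channel mean, rescale by the ratio of target to tile standard
deviation, add the target mean — followed by conversion back to RGB with
gamut clipping. This is the *fast* variant: no separate brightness
standardization step precedes the transfer; the luminance channel simply
participates in the same affine map. Before clipping, the output's lαβ
moments equal the fit targets exactly; clipping perturbs them by well under
2% on tissue tiles.

The normalization target ("fit") is either computed from a user-supplied
reference image or taken from the package preset: the lαβ statistics of a
deterministic synthetic H&E-like reference tile built by the package's own
generator. Upstream libraries ship opaque preset constants; ours are
reproducible from code. Normalization happens at train/inference time on
bag tiles and is never baked into tile stores.

## The MIL classifier

Tiles are grouped into bags that inherit the slide's label. The full-scale
recipe is bags of 100 from 200 random tiles per slide (two bags per slide);
tiles are drawn without replacement while the store lasts and topped up
with replacement, so every slide yields the same number of bags.

The network has three parts:

* a **frozen backbone** — `small_cnn`: the input is average-pooled 4×, then
  passed through three randomly-initialized (He, seeded) 3×3 convolution
  blocks of 8, 16 and 32 filters with ReLU and average pooling, ending in a
  global average pool. Its 32-dimensional descriptor is never trained.
  Random convolutional features are a well-studied, surprisingly strong
  texture descriptor, and freezing them mirrors the transfer-learning
  pattern of freezing a pretrained trunk. A pretrained large backbone would
  need downloaded weights and a deep-learning runtime; the pipeline's logic
  is independent of the trunk, which is why the backbone is pluggable.
* a **descriptor standardization**: per-dimension mean and standard
  deviation of the training tiles' descriptors, estimated once at the start
  of training and stored with the model (never optimized). GAP-of-ReLU
  descriptors are all-positive with large common-mode means; without
  centering, single-class bag gradients nearly cancel and AdamW stalls.
* the **trainable head** — a 1×1 projection layer (the "last convolutional
  layer" of the network, width D = 64, ReLU), arithmetic-mean pooling of
  the projected tile features over the bag, and a linear classification
  layer to two classes. Both are Xavier-initialized from the seed.
  Mean pooling makes the bag representation order-invariant; attention
  pooling is deliberately out of scope.

Training minimizes bag-level cross-entropy with AdamW (learning rate 1e-3,
decoupled weight decay 0.01). Batches are expressed in tiles (64 by
default) and grouped into whole bags per optimizer step. Augmentation is
independent horizontal/vertical flips with probability 0.5 per tile;
inference applies none. Tiles are standardized per channel (ImageNet
statistics by default). Early stopping watches patient-level validation
accuracy with patience 20 within at most 100 epochs; among epochs tied on
the metric, the snapshot with the lowest validation loss is kept (tiny
validation sets saturate the accuracy metric immediately, and the
lower-loss model has the wider margins). Everything — initialization, bag
draws, flips — derives from one seed, so runs reproduce bit-for-bit, and
the frozen backbone is byte-identical before and after training.

At inference a slide's probability is the arithmetic mean of its bags'
probabilities (a mean of simplex points stays on the simplex); per-tile
probabilities are obtained by pushing each tile through the head as a bag
of one. How several bags combine into one slide prediction is not dictated
by the aggregation rule below, which operates on slides; averaging is the
natural choice consistent with it.

## Patient-level aggregation and metrics

Patients can own several slides, and some own slides of *both* classes
(a tumor section and a normal-tissue section). Each (patient, class) pair
is treated as an independent entity. For an entity with N > 1 slides the
final probability is the componentwise mean of the slide probabilities
passed through softmax; with a single slide, that slide's prediction *is*
the patient-level prediction — no softmax. The two branches genuinely
differ (softmax would re-map (0.9, 0.1) to about (0.69, 0.31)); the
single-slide-direct rule is the default and the softmax-always behavior is
available behind a flag.

Metrics are always computed at the entity level: accuracy and the confusion
matrix from the argmax (ties resolve to tumor, the conservative call in
screening), binary F1 with tumor positive, and rank-statistic AUC (half
credit for ties). Single-class evaluations report AUC as undefined rather
than a number.

## Cross-validation and protocols

Folds partition entities, stratified by class to within one entity, and
both entities of a dual-class patient are co-assigned to one fold, so
train/test patient-id intersections are empty by construction. (The
alternative — letting a patient's two entities land in different folds —
is defensible since they depict different tissue, but it would breach the
stronger no-patient-overlap guarantee this package asserts on every run.)
Within a fold's training portion, entities are split 80–20 into train and
validation. A grouped mode builds one fold per value of a grouping column
(e.g. country), each test fold pure in its group.

Three protocols are provided: k-fold CV on one cohort; train on one (or a
pool of) cohort(s) and test on another; and train on a pooled set with an
external holdout. Every protocol run asserts patient-id disjointness
before fitting and shares the frozen backbone and per-slide descriptor
tables across folds.

## Batch-effect diagnosis

Slide representations (mean over bags of the pre-head pooled feature) are
examined with k-nearest-neighbor label purity: for each slide, the
fraction of its k = 10 Euclidean neighbors sharing its label, averaged over
slides — once for the class label and once for the dataset label. The
difference, `confounding_index = purity_dataset − purity_class`, is
positive when neighborhoods organize by origin more than by biology.

One structural property deserves emphasis: neighbor pairs whose class
labels and dataset labels agree simultaneously contribute identically to
both purities, so the index is bounded by (roughly twice) the fraction of
slides whose class disagrees with their dataset's majority class. On a
heavily confounded pool — the very situation the index is meant to flag —
that fraction is small by definition, and the index stays near zero even
when features encode nothing but the dataset. The index therefore
discriminates *between models* (relative comparisons on the same slides)
better than it serves as an absolute yardstick; absolute thresholds on the
order of 0.2 are only reachable when the evaluated slides contain
substantial class variation within datasets. A 2-D embedding (Laplacian
eigenmaps on the symmetrized kNN graph — deterministic, no stochastic
optimizer) is provided for plotting only; no quantitative claim is read
off the embedding.

# The synthetic multi-center scenario

`cohort_spec()`/`generate_slide()` produce slides with: a near-white
background (gray ≈ N(242, 4²)) so the gray histogram is cleanly bimodal; a
contiguous elliptical tissue region of configurable area fraction (default
0.75; fractions ≥ 0.99 keep a background strip of 1/8 of the rows so Otsu
retains a background mode); a pink/purple tissue base with iid noise; and
dark elliptical nuclei-like spots whose density and radius carry the class
signal — tumor doubles the density and scales the radius 1.5× by default.
The spot color is a *moderately* dark purple: the class signal is density,
and the spot mode must stay closer to the tissue base than the base is to
the background, otherwise the dominant between-class-variance split of the
histogram would sit at the spot/tissue boundary and Otsu masking — which
assumes the background/tissue split dominates — would collapse. Tumor
slides keep control texture on 20% of their tissue (a tumor-purity default;
real tumor sections contain normal tissue, which is also why per-tile
predictions on tumor slides are legitimately mixed).

Dataset identity is a *presentation fingerprint* applied per dataset:

* a global color cast — per-channel multiplicative and additive shift on
  tissue pixels, clipped to [0, 255]. This is the component stain
  normalization targets, and per-tile Reinhard transfer removes it almost
  entirely (the package measures this: the inter-dataset mean tile color
  distance shrinks by far more than half after normalization);
* a hematoxylin intensity (`spot_gain`) scaling spot darkness relative to
  the base — largely neutralized by the variance-matching half of the
  affine transfer;
* an apparent cellularity (`density_gain`) and structure size
  (`radius_gain`) — spatial properties of the tissue rendering, emulating
  differences in tissue source and preparation (surgical resections vs.
  autopsy material, scanner resolution, fixation shrinkage). Per-tile
  *color* normalization cannot touch these, which is precisely why
  integrated datasets remain distinguishable after stain normalization.

The `confounded_trio` preset mirrors a three-source study: cohort A is
tumor-heavy (20 tumor : 2 control patients), cohort B is control-only (20),
cohort C is balanced (12 : 12, with one in six patients owning a slide of
each class), and cohort T is a small balanced holdout (5 : 5) with disjoint
patient ids. A and B carry strong opposing color casts *and* opposing
preparation scales (A: dense, large structures; B: sparse, small), so
within A+B both class cues — absolute spot density and absolute spot size —
are contaminated by the dataset scale, and the class remains almost
perfectly predictable from the fingerprint alone even after normalization.
C and T share a common, milder preparation scale sitting outside the
A/B interpolation: a model calibrated to the integrated A+B scale places
its decision boundary above C's tumors (A's *control* slides are denser
and larger-structured than C's *tumor* slides), while within C the 2× /
1.5× class ratios stay cleanly learnable and C-trained models transfer to
T. With the fingerprint knob off (identity casts), color and scale carry
no dataset signal and the confounded-training gap closes — the downstream
check of the generator's confounding contract. Slides are regenerated on
demand from the manifest (deterministic per-slide seeds), so cohorts of
any size never need to sit in memory.

What the generator does *not* emulate: realistic nuclear morphology,
stain-vector (absorbance) physics, magnification pyramids, or artifacts
(folds, pen marks, blur). Passing tests on this generator demonstrates the
pipeline's logic — masking, filtering, leakage guards, learning,
aggregation, diagnosis — not performance on real tissue.

# Study conditions used by the tests and the acceptance script

Desk-scale experiments use 1024×1024 slides (a 4×4 tile grid, of which
roughly 10–12 central tiles survive filtering), bags of 8 from 16 tiles per
slide — two bags per slide, as in the full-scale recipe — one bag per
optimizer step, at most 40 epochs with patience 10, 5-fold CV on cohort C,
and Reinhard normalization (package preset) on, as the full-scale recipe
trains. Stochastic claims (learning sanity, the confounding experiment) are
asserted as a majority over three seeds. The acceptance script runs the
same experiment once at a user-supplied seed and reports: the CV accuracy
on C, the accuracy of the A+B-trained model on C and the resulting
generalization gap, the C-trained and pooled-model accuracies on the
holdout T, the two confounding indices on A+B features, and the fraction of
the inter-dataset color distance removed by Reinhard normalization.

# Known limitations and open choices

* The upstream preset constants of the original normalization library are
  not recoverable; the package preset is its own deterministic reference.
  Results are therefore comparable within the package, not to pipelines
  using other presets.
* `resnet50_imagenet` appears in the configuration vocabulary as the
  full-scale backbone of the recipe this package operationalizes, but this
  build provides only `small_cnn`; plugging a pretrained trunk in requires
  a deep-learning runtime and its weights.
* The validation metric for early stopping (patient-level accuracy), the
  weight-decay coefficient (0.01), the over-cap tile selection rule and the
  low-contrast threshold are package decisions where common practice varies.
* The confounding index has the composition ceiling described above; its
  absolute level on a confounded pool should be read against that ceiling,
  and model comparisons should be made on identical slide sets.
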