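---
title: "Methods: interpretable feature-based staging of Ta versus T1 bladder tumor histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable feature-based staging of Ta versus T1 bladder tumor histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-invasive papillary (Ta) and superficially invasive (T1) bladder tumors can
look very similar on hematoxylin-and-eosin (H&E) sections, yet the distinction
drives treatment. Three microscopic patterns are associated with invasion:
a **desmoplastic reaction** (dense fibrous stroma crowded with inflammatory
nuclei around tumor nests), **retraction artifact** (thin empty clefts around
nests left by tissue shrinkage during processing), and **more abundant, pinker
cytoplasm** (higher eosin uptake by invasive tumor cells). `hestage`
operationalizes each pattern as a fixed block of quantitative image features,
feeds the assembled feature table to interpretable classifiers, and evaluates
them under a balanced repeated-split protocol. Every stage is exercisable end
to end on a built-in synthetic H&E phantom generator with pixel-level ground
truth, so the whole pipeline is testable without access to clinical slides.

## Image model and preprocessing

Images are 8-bit RGB arrays, row-major with the origin at top-left. Large
captures (nominally 2048 x 2048 at 100x magnification) are reduced to a
centered grid of at most four 700 x 700 tiles (`crop_center_tiles()`); tiles
whose tissue fraction falls below 5% are dropped, keeping at least the single
most tissue-rich tile. The source protocol cuts "1 to 4" central tiles without
stating the per-image rule; the tissue-fraction criterion is this package's
choice and is exposed in `stage_config()`.

Illumination is corrected by flat-field division (`flatfield_correct()`): a
per-channel low-frequency field is estimated with an FFT-domain Gaussian
low-pass (mirror padding, so no wrap-around artifacts) applied to a 10x
downsampled copy of the channel, and the channel is divided by the field and
rescaled to preserve its global mean. The Gaussian scale defaults to 1/16 of
the image side: we verified on constructed inputs that this scale reduces the
coefficient of variation of a corner-to-corner linear gradient by more than
10x and flattens a dark lower-right Gaussian vignette (a known artifact of
the capture setup being emulated) to within 5% between corner and center
quadrants, while leaving a constant image exactly fixed. Substantially larger
scales track neither artifact well; substantially smaller scales start eating
real tissue texture.

Tissue is separated from background by luminance thresholding
(`tissue_mask()`): a pixel is non-tissue iff `round(0.299 R + 0.587 G +
0.114 B) >= 220`, since H&E non-tissue (empty slide, clefts, gaps) is
near-white. A closing with a radius-2 disk removes salt noise. The crack
segmenter deliberately binarizes *without* that closing, because a radius-2
closing fills exactly the 1-5 px clefts it must measure.

## The three pattern extractors

**Retraction artifact** (15 features). The non-tissue mask is labeled with
8-connectivity (thin diagonal cracks stay connected) and each component is
sized by its *equivalent circular diameter* `2 sqrt(area / pi)`. Components
strictly larger than 40 px in diameter are inter-tissue space; the remainder
are peri-cellular cracks. The strict inequality follows the protocol's
"more than 40 pixels in diameters" rule; a maximum-Feret alternative is
available behind `diameter_method = "feret"` and both are oracle-tested.
Border-touching components are classified by the same rule. The 15 features
cover crack pixel counts and fractions, component-area statistics, total
crack perimeter ("crack edge") and its density per tissue area, elongation,
mean width, and two background features (`sample_ratio`,
`nontissue_fraction`). Mean width is the ribbon approximation
`area / (perimeter / 2)`; no installed package provides skeletonization, and
for bands of near-constant width the two definitions agree to first order.

**Pinker cytoplasm** (13 features). Cytoplasm is tissue minus nuclei. Each
cytoplasm pixel gets a pinkness index `p = (R - B) / 255` in [-1, 1] — red
excess over blue, which tracks eosin against the hematoxylin direction while
ignoring green. The block is an 8-bin histogram of fractions over [-1, 1]
plus mean and standard deviation of `p`, the red/blue mean-intensity ratio,
and two background features. The source work chose a color-spectrum bin size
empirically without reporting it; 8 uniform bins are fixed here in config.
Color deconvolution into stain optical densities would be the heavier
alternative; the index was chosen because it is parameter-free and exactly
testable.

**Desmoplastic reaction** (675 features). Nuclei are hematoxylin-dominant
pixels (`B > R + 15` and luminance < 180), opened with a radius-1 disk
(the 5-pixel cross), labeled with 8-connectivity, and filtered at 20 px
minimum area; watershed splitting of touching nuclei exists but is off by
default because the emulated protocol never mentions it. Per-nucleus records
carry 14 shape measures, 15 per-channel intensity statistics, and 2
neighborhood measures (nearest-neighbor distance, neighbor count within
50 px). The 675-feature block aggregates each per-nucleus measure over the
image by 8 statistics (mean, median, sd, MAD, min, max, quartiles) and adds
image-level counts and a 16-bin nucleus-area histogram, stromal gray-level
co-occurrence texture (13 statistics x 4 angles x 3 offsets on 8 gray
levels), stromal per-channel 32-bin intensity histograms, connective-tissue
object shape aggregates, a 16-radius granularity spectrum of the nucleus
mask (fraction of nucleus pixels whose distance transform exceeds r), and
28 auxiliary intensity summaries. The exact composition of the 675 features
is not recoverable from the emulated study; this manifest is a
reconstruction with the correct cardinalities, committed as
`inst/extdata/feature_manifest.csv` and asserted in tests.

Two perimeter notions coexist deliberately. The `perimeter` feature is the
exposed-pixel-edge count — exact and verifiable against a brute-force oracle.
For `form_factor = 4 pi A / P^2`, the edge count would give a disk ~0.6, so
the form factor uses a corner-corrected estimate (`edges - (2 - sqrt(2)) *
corners`, floored at the equal-area-circle perimeter), which scores digital
disks at ~1 and keeps the measure in (0, 1]. Ellipse axes come from second
moments with the per-pixel 1/12 term, so a 1-px line has a positive minor
axis and eccentricity strictly below 1.

## Feature schema: 740 raw columns, 696 analysis features

The raw export always carries 740 columns: 696 numeric features plus 44
metadata/invalid columns (timestamps, image/tile indices, descriptive
strings, and measurements like mean gap intensity that are undefined — `NA` —
when their mask is empty). The emulated study's Methods (60 + 636 = 696
extracted) and Results (740 extracted) state different counts; the schema
reconciles both by treating 740 as the raw export width and 696 as what
survives cleaning. `clean_features()` drops the 44 metadata columns plus any
numeric column containing a missing value, and is idempotent.

The 696 features form three overlapping pattern groups of 675 / 13 / 15.
Seven global "background" features belong to two groups each (sample ratio
and non-tissue fraction to retraction + desmoplastic; the five global
stain/intensity summaries of the cytoplasm block to cytoplasm +
desmoplastic), so group memberships sum to 703 over 696 unique columns.
Shared features are computed once and written once; membership is schema
metadata, not duplication.

## Feature ranking and classifiers

Feature importance is estimated by 20 independent forests of 40
classification trees. Each tree is grown on a bootstrap sample of rows with
*all* features available at every split — no column subsampling, which is
what distinguishes this design from a default random forest — and importance
is the total Gini impurity decrease credited to each feature. Forest-level
importance vectors are normalized to sum 1 before averaging so every forest
weighs equally; ties break by manifest column order. `select_top_k()` takes
the leading 100 by default, and `incremental_curve()` reproduces the
features-added-in-rank-order accuracy curve.

Six classifiers are exposed: **PNN**, **SVM** (RBF kernel), **LR**
(L2-regularized logistic regression), **Bagging** (resolved as AdaBoost over
depth-1 trees, written in-package; a true bagging of full trees is available
as `BaggedTrees`), **RF** (100 trees), and **MLP** (one hidden layer of 100
units). Hyperparameters are conventional defaults — the emulated study states
none — and all are overridable through the `config` argument.

The probabilistic neural network is implemented from scratch as a
Parzen-window Bayes classifier: class score
`g_c(x) = (1/n_c) sum_i exp(-||x - x_i||^2 / (2 sigma^2))` over stored
standardized training vectors, posterior proportional to `prior_c * g_c`,
computed in log space with log-sum-exp stabilization so small bandwidths
cannot underflow. The default bandwidth is 0.1 times the median pairwise
training distance — a scale that adapts to dimension and sample size; the
posterior invariants (rows sum to 1, nearest-neighbor behavior as
`sigma -> 0`) are tested.

## Evaluation protocol

Each of 20 repeats: (i) balance the classes by subsampling the majority to
the minority count without replacement (emulating the 460 + 460 design);
(ii) split the balanced rows 70/30 with no row in both sets; (iii) fit;
(iv) score held-out rows with the invasive-class probability (classifiers
without native probabilities use a min-max-scaled decision value); (v) record
accuracy at threshold 0.5, the ROC curve, and the trapezoidal AUC — which is
proved equal to the Mann-Whitney pairwise statistic in the test suite. The
mean ROC band is formed by vertical averaging of per-repeat step-function
ROCs on a fixed 101-point false-positive-rate grid, with a pointwise
standard deviation. A repeat whose test split lacks a class is redrawn from
the next seed substream and logged. All randomness flows from one integer
seed through a multiplicative substream derivation, so every result is
bit-reproducible.

## Unsupervised analysis

`pca_features()` centers and (by default) standardizes the features —
they mix pixel counts, ratios and intensities, so unit variance is the
defensible default — dropping constant columns first. `kmeans_sweep()` runs
Lloyd's algorithm with k-means++ seeding, best of 10 restarts by
within-cluster sum of squares, over k = 2..9 on enough leading components to
reach 90% cumulative eigenvalue mass (capped at 50). Cluster quality against
the stage labels is the information gain
`H(labels) - sum_j (n_j/n) H(labels | cluster j)` in bits, reported per k
(the emulated study did not say which k its figure refers to).

## The synthetic phantom generator

`phantom_spec()` / `generate_phantom()` rasterize a 700 x 700 scene: a pink
eosin canvas, dark blue hematoxylin nuclei as hard disks (a pixel belongs to
a nucleus iff its center is within the radius — no anti-aliasing, so areas
are oracle-computable), thin white crack bands (width 1-5 px) drawn around
well-separated nuclei, and white inter-tissue gaps (90 px diameter, safely
above the 40-px rule, while crack components stay safely below it, so
ground-truth classes are unambiguous by construction). Ground-truth masks
are frozen before a multiplicative illumination field (planar gradient with
random orientation, peak-to-trough 15%, plus a dark lower-right Gaussian
vignette) and additive Gaussian noise (sd 3, clipped to [0, 255]) are
applied — extractors are therefore validated against pre-illumination truth.

The default class conditions encode the three patterns at what we consider
realistic relative strengths: Ta has ~60 nuclei of mean radius 7 px, crack
fraction 1%, no pinkness shift; T1 has ~120 nuclei of mean radius 9 px
(the crowded desmoplastic stroma), crack fraction 1.8%, and a +8 red-channel
shift of the cytoplasm. Per-image nuisance variation — a per-channel color
jitter of sd 5 emulating staining variability, and a lognormal (sdlog 0.35)
jitter of the crack fraction — makes the cytoplasm and retraction signals
genuinely overlap between classes while the nucleus-count signal stays
strong. This mirrors the qualitative ordering reported for real slides
(desmoplastic features most predictive; cytoplasm and retraction each
informative but weaker) without attempting to reproduce clinical accuracy
values, which belong to a proprietary 1177-image dataset that is not
available. What passing tests show is that the *pipeline* recovers planted
structure correctly; they cannot show that the phantoms capture the full
biological variability of real H&E slides — no texture within stroma beyond
the generated patterns, no touching nuclei by default, no stain vector
variation beyond channel jitter, no out-of-focus or fold artifacts.

## Problem sizes and numerical choices

The shipped study sizes were chosen so a complete run stays comfortable on a
single CPU: the end-to-end analysis uses 100 phantoms per class (the
acceptance script and the deepest test), oracle-agreement suites use 1000
random 64 x 64 phantoms and 1000 random score sets, and the ranking-recovery
suite uses 20 reseeded runs of the full 20 x 40 forest design on a 200 x 100
table. The label-permutation (no-leakage) suite uses a 1000-row table: a
single fixed permutation of a small table retains finite-sample feature-label
correlation of order `1/sqrt(n)` that flexible classifiers legitimately
exploit, so the chance-level check needs n large enough for that term to be
negligible. Degenerate inputs are all defined rather than erroneous: empty masks
yield zero-valued features (with a warning when a density's denominator is
empty tissue), aggregate statistics of empty record sets are 0, and the
single surviving failure modes — packing too many nuclei into a tile,
single-class labels, k larger than the number of rows — raise explicit
errors.

## Known limitations

- The 675-feature manifest is a faithful-cardinality reconstruction, not the
  original tool-by-tool export, so individual feature values are not
  comparable to the emulated study's spreadsheets.
- The pinkness index is a channel contrast, not stain deconvolution; slides
  with atypical stain vectors would need the deconvolution extension.
- Forest importance is computed per forest (40-tree aggregate) rather than
  per tree before normalization; with all features available at every split
  the two weightings differ only marginally.
- The k-fold cross-validated variant of tree ranking mentioned in passing by
  the emulated study is not reproducible from its description and is out of
  scope.
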