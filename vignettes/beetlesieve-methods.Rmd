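---
title: "Disaggregation, open-set scoring and evaluation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disaggregation, open-set scoring and evaluation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetlesieve)
```

`beetlesieve` packages a complete workflow for identifying insect specimens
from multi-specimen photographs: segmentation of composites into
single-specimen crops, transfer-learning classification, a dispersion-based
unknown-class probability, leakage-free splitting, and a leave-one-class-out
open-set evaluation harness. This vignette documents the models, the tunable
parameters, the numerical choices, and — because several of them were
genuinely open — the design decisions and what the green tests do and do not
establish.

## 1. The segmentation model and its assumptions

The disaggregation procedure assumes laboratory-style photographs: dark,
compact specimens on a light, approximately uniform background, with the
whole dish in frame. Under those assumptions the eight-step procedure is
essentially parameter-free:

1. load the color composite;
2. grayscale by the BT.601 luminance weights (0.299, 0.587, 0.114) — any
   fixed convex weights would do, this is the convention the common imaging
   stacks use;
3. binarize at Otsu's threshold, computed on a 256-bin histogram, with ties
   broken toward the lower bin for determinism; specimens are the
   *below*-threshold pixels;
4. delete every foreground component with a pixel on the image border
   (partial specimens cannot be classified);
5. label 8-connected components and record exact areas and tight bounding
   boxes (8- rather than 4-connectivity so that thin diagonal junctions do
   not split a specimen; one consistent choice is used everywhere);
6–7. split object areas into two clusters and keep the cluster with the
   larger mean — specimens versus debris;
8. crop the kept boxes (0-based, half-open coordinates; default margin 0)
   from the original color image.

Two numerical details deserve a note. First, the size filter is implemented
as the *exact* minimum-SSE two-partition of the areas (an exhaustive scan
over the n−1 threshold splits of the sorted areas) rather than Lloyd
iterations from a heuristic initialization: in one dimension the k-means
optimum is a threshold partition, so the exhaustive scan *is* the converged
two-means solution, with no dependence on initialization. Degenerate inputs
(fewer than two objects, or all areas identical) keep everything — erring
toward keeping specimens. Second, Otsu's threshold is only meaningful for
bimodal histograms; an object-free image (background noise only) would
otherwise be split down the middle of its noise distribution. `disaggregate()`
therefore computes Otsu's effectiveness ratio (between-class variance over
total variance; about 0.75 for unimodal distributions, near 1 for true
object/background contrast) and reports images below 0.8 as object-free
rather than emitting noise crops. A constant image is likewise reported
degenerate rather than raising an error.

The original workflow removed multi-specimen and partial crops by manual
inspection. Manual review cannot live inside a package, so crops whose boxes
overlap another kept box (`touching_another_box`) or whose aspect ratio is a
robust outlier (median absolute deviation rule) are *flagged* in the crop
manifest for human review instead of silently dropped.

## 2. The unknown-class probability

A closed-set softmax classifier must put probability somewhere even for an
input from an untrained class. The package's open-set score uses only the
shape of the probability vector. With threshold `t` in (0, 1):

\[ d_i = P_i^{\,1-|P_i-t|}, \qquad
   P_u = 1 - \frac{\sum_i\sum_j |d_i-d_j|}{2\,(n-1)\sum_j d_j}. \]

The ratio subtracted from 1 is the Gini-type normalized mean absolute
difference of `d`, which is 1 exactly when `d` is one-hot and 0 exactly when
all `d_i` are equal; hence `P_u` hits 0 (one certain class) and 1 (nothing
stands out) exactly, and the standard mean-absolute-difference bound keeps it
in [0, 1] always. The typeset form of this formula in the source material
has inconsistent summation indices; the implementation commits to the reading
above because it is the unique natural one that reproduces both stated
limiting behaviors *exactly*. That interpretation is a design decision, not a
transcription.

The exponent `1 − |P_i − t|` lies in (0, 1], so `d_i` is well defined with
`0^positive = 0`; `t = 0` and `t = 1` are rejected (at `t = 1` the expression
`0^0` would arise). The operational default is `t = 0.8`, the threshold the
deployed tool uses. The decision rule for the formula method compares `P_u`
against a second threshold `t_open` that defaults to `t` but is separately
configurable — the source material never states whether the two coincide.
The conventional baseline (`unknown` iff `max(P) < t`) shares the interface;
both expose an `unknown_score` oriented so that larger means more unknown
(`P_u`, respectively `1 − max(P)`), which lets one ROC implementation serve
both. Argmax ties break to the lowest class index.

Vectorized evaluation uses the sorted-order identity
\(\sum_{ij}|d_i-d_j| = 2\sum_k (2k-n-1)\,d_{(k)}\) and is tested to 1e-12
against a naive double loop.

## 3. Splits

The unit of assignment is the *group*: one physical dish and all of its
agitation replicates, because the same individuals appear in every replicate.
The test draw is per class with largest-remainder rounding of
`test_frac × groups`, a minimum of one test group where the class has at
least two, and singleton-group classes kept entirely in train (with a
warning) so the closed-set test never contains a class absent from training.
Whether the original 20% draw was per-class exact or global is not stated;
per-class is the stricter reading and is what is implemented. Remaining
groups are dealt into k folds per class round-robin (with a rotating start
so small classes do not pile into fold 1), which bounds per-class fold-count
differences by one. All randomness flows through an internal seeded RNG that
neither reads nor disturbs the caller's RNG state.

## 4. Training

The classification head is `linear → tanh → softmax`: pre-softmax activations
are bounded in [−1, 1], so no predicted probability can reach 0 or 1 — the
extreme achievable probability is \(e/(e + (n-1)e^{-1})\) (about 0.787 at
n = 3, 0.88 at n = 12). The loss is label-smoothing cross-entropy with the
canonical uniform target \(q_i = (1-\varepsilon)\,[i=y] + \varepsilon/n\),
\(\varepsilon = 0.1\) by default (the source names the loss but not its
parameters); probabilities are clamped at 1e-12 inside the log, a safety net
the tanh head makes almost unreachable. The schedule is one warm-up epoch
with every backbone parameter frozen (asserted bit-exactly in the tests),
then full fine-tuning with Adam. Defaults: batch 64, 5 epochs, learning rate
0.003, input 224×224, augmentation probability 0.8 — the tuned values of the
original recipe. An optional plateau rule (patience on validation loss) is
available but off by default.

Augmentations: rotation ±15°, horizontal/vertical flips, zoom and per-axis
scaling in [0.9, 1.1], shear ±0.1, random crop retaining ≥ 80% of the area
(the geometric parts compose into a single bilinear affine resampling),
brightness ±0.2, contrast ×[0.8, 1.25], Gaussian blur, and random noise
patches covering ≤ 5% of the area; each is applied independently with the
configured probability. Magnitudes are package defaults — the source states
the augmentation families and the 0.8 probability but no magnitudes. One
subtlety: the blur magnitude (σ up to 2 px) is meaningful at the 224-px
reference resolution; applied verbatim to a 30-px crop it would erase the
image. σ therefore scales with the working resolution relative to 224. The
resize policy is direct squash to the square input (configurable; padding
would preserve aspect ratio, which the source does not discuss).

**The backbone is pluggable and that matters.** The original deployment
fine-tunes a 116M-parameter pretrained vision transformer; no such
checkpoint can ship in an offline package, and the pipeline's contribution
is everything around the backbone. The built-in `tiny_cnn` is a one-layer
patch convolution (stride = kernel = 4 on a 32-px grayscale rendition,
shared weights, tanh) pooled by first and second moments over patches, plus
eight fixed radial-profile features (ring means and standard deviations —
rotation- and flip-invariant, and exactly the right inductive bias for the
concentric markings of the synthetic world). Two data-dependent but
deterministic initialization steps stand in for pretraining: per-feature
whitening constants estimated once from the training images, and a
closed-form ridge-regression initialization of the head on those whitened
features. Without them, five epochs of Adam at learning rate 0.003 — a
schedule tuned for *fine-tuning a pretrained network*, a few dozen optimizer
steps at this data scale — cannot train a from-scratch network to
convergence; with them, the schedule does what it does in the original
recipe: refine an already-informative representation. Both steps happen at
initialization, so the warm-up freezing contract (backbone bit-identical
through epoch 1) is unaffected. An `external` backbone slot accepts any
user-supplied feature-extractor closure.

## 5. Evaluation

ROC curves treat "unknown" as the positive class, sweeping every distinct
score; AUC is trapezoidal and is property-tested against the Mann-Whitney
pairwise concordance oracle, including ties. Fold averaging is vertical:
each curve is evaluated as a right-continuous staircase on a common 101-point
FPR grid and averaged pointwise (thresholds are interpolated the same way);
"average of the ROC curves" admits other readings, but vertical averaging is
the standard one. The operating point is the curve point closest in Euclidean
distance to (FPR 0, TPR 1), ties toward the lower threshold (favoring recall
of unknowns). Weighted F1 treats "unknown" as an ordinary additional label,
weighting per-class F1 by true support.

The leave-one-class-out protocol trains, for every class and every fold, on
the other folds with that class excluded, and scores the held-out fold's
knowns plus *all* crops of the excluded class (relabeled "unknown"). Both
scoring methods read from the same cached prediction matrix, so their
comparison is apples-to-apples; a manifest audit asserts that no
excluded-class crop ever reaches a training batch. Which material beyond the
excluded class served as "unknown" test data in the original study is not
fully specified; held-out knowns plus the full excluded class is the
implemented choice.

## 6. The synthetic world

The generator produces what the segmentation algorithm actually sees:
textured dark ellipses of a single class per dish on a near-white background
(intensity 0.95, Gaussian noise σ 0.01), some ellipses crossing the image
border, and small debris specks (6–18 px, far below a tenth of the smallest
specimen). Batches emulate physical dishes: each batch draws its objects once
and re-renders them at fresh positions and orientations per replicate, as
agitation would, with all replicates sharing a `group_id`. Default scale: 4
classes, 320-px composites, 8 interior specimens, 2 edge objects, 3 debris.

Class signatures were chosen once, with two constraints pulling in opposite
directions. (i) *Separability:* classes must be reliably learnable — mean
areas follow a geometric ladder (300, 570, 1009, 1752 px) with adjacent
means ≥ 5 generator standard deviations apart, so a linear classifier on
ground-truth (area, intensity) exceeds 99% accuracy, the floor that makes
training-module acceptance meaningful. (ii) *Open-set realism:* the original
study evaluates unknown detection on congeners closely related to the
training classes; an excluded synthetic class must therefore resemble the
remaining ones rather than extrapolate beyond them. A one-dimensional trait
ladder fails this badly — the end classes extrapolate and are *confidently*
misclassified, which no post-hoc score can repair (early experiments with an
intensity ladder produced inverted ROC curves for the extreme classes,
exactly as open-set theory predicts). The final design gives every class the
same body intensity (0.40) and distinguishes classes by concentric dark
marking patterns — central disc, mid annulus, rim, disc+rim — so each
left-out pattern is a sub- or super-position of patterns still in training
and lands near decision boundaries instead of deep inside one class's cone.
Markings are coarse on purpose: a fine texture cue would not survive the
blur/contrast augmentation regime, making closed-set training needlessly
fragile.

What a green acceptance run establishes: the pipeline's numerics are exact
against independent oracles; segmentation recovers ≥ 95% of true specimens
at IoU ≥ 0.8 while excluding all border objects and ≥ 95% of debris; splits
leak nothing; and on this synthetic world the full leave-one-class-out loop
reaches macro-F1 ≥ 0.95 closed-set and fold-averaged unknown-detection
AUC ≥ 0.9 for both scoring methods. What it does not establish: performance
on real photographs — reflections, shadows, touching specimens, uneven
lighting, genuinely continuous morphological variation — or the original
study's headline numbers, which depend on its dataset and pretrained
backbone.

## 7. Known limitations

- Touching specimens merge into one blob; like the original procedure, the
  package only flags (bounding-box overlap) rather than splits them.
- The low-contrast guard (effectiveness < 0.8) is a heuristic; unusual but
  legitimate bimodal images with weak contrast would be reported object-free.
- The unknown-class probability is a function of the probability vector
  alone; a confidently wrong prediction on an out-of-class input (feature
  extrapolation) defeats it and the max-probability baseline alike.
- Image I/O is plain-text PNM in this build, chosen because no binary image
  codec is available in the target environment; all in-memory interfaces are
  format-agnostic and a PNG/TIFF reader could be swapped in where available.
- Config files are JSON (same reason: no YAML parser in the environment);
  the schema is strict and every protocol constant is a named, overridable
  default.
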