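---
title: "A size-aware 2D segmentation pipeline for TOF-MRA aneurysms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A size-aware 2D segmentation pipeline for TOF-MRA aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mraseg)
```

## The problem

Intracranial aneurysms appear on Time-of-Flight MR angiography (TOF-MRA) as
focal hyperintense outpouchings on bright vessels. The clinically hardest
cases are lesions under 3 mm: at typical in-plane spacings of about 0.5 mm
they occupy a few dozen pixels and may intersect only one or two axial
slices, so a 2D instance-segmentation detector (Mask R-CNN-style) tends to
suppress them during score filtering and non-maximum suppression. `mraseg`
implements the data-engineering and post-processing logic of such a
pipeline — everything around the detector itself — with the detector behind
an adapter contract so the whole system is testable on one CPU.

## Preprocessing model

Volumes arrive as 3D NIfTI with voxel spacing in the header. Each volume is
cut along the third (axial) axis and every image slice is min-max rescaled
to 8-bit:

$$I_{norm} = \mathrm{round}\!\left(\frac{I - I_{min}}{I_{max} - I_{min}}
\times 255\right)$$

Two choices deserve comment:

* **Per-slice statistics.** The rescale is defined per image, and slices
  are the training images here, so $I_{min}, I_{max}$ are per-slice by
  default. This maximizes per-slice dynamic range but discards cross-slice
  intensity comparability; `normalize_volume()` (and the CLI flag
  `--per-volume-norm`) offers volume-wide statistics for users who prefer
  the opposite trade-off. The choice is a genuine toss-up for detection
  performance; the per-slice default is the one this package commits to.
* **Degenerate slices.** A constant slice (pure background at the top or
  bottom of a head volume) has $I_{max} = I_{min}$; it maps to all zeros
  rather than erroring, so batch conversion never aborts.
* **Rounding.** All quantization uses round-half-up (`floor(x + 0.5)`),
  deterministic across platforms, unlike banker's rounding.

Skull stripping is an upstream concern: the package consumes
already-stripped volumes and never invokes an external brain-extraction
binary.

## Augmentation operators

Offline dataset expansion, each source slice yielding the original plus one
copy per operator:

* **Rotation** by $\pm 15^\circ$ about the image center, using the standard
  planar rotation matrix with translation terms that keep the center fixed.
  Images are resampled bilinearly, masks nearest-neighbor — bilinear
  resampling of a mask would create fractional labels, and nearest keeps
  masks strictly binary. Output frames keep their shape; uncovered corners
  fill with 0.
* **Contrast** $I' = \alpha I + \beta$ with $\alpha = 0.5$,
  $\beta = -100$. With these values every intensity up to 200 clips to 0:
  the operator deliberately suppresses the dominant bright vessel signal so
  low-contrast lesion neighborhoods dominate the remaining range. Clipping
  happens before rounding, since $\beta = -100$ drives much of the image
  negative.
* **Gamma** $I' = 255 (I/255)^{1/\gamma}$ with $\gamma = 2$, a mid-range
  brightening with 0 and 255 as fixed points.
* **Gaussian noise**, optional, default $\sigma = 5$ on the 0-255 scale
  when enabled. The magnitude of "low-level" noise is not standardized, so
  it is a configurable parameter; 5 is roughly 2% of the dynamic range,
  visible but far below lesion contrast.

Reflections are deliberately absent: left-right or up-down flips of brain
anatomy are off-distribution and were excluded from the operator set.
Photometric operators never touch masks (bit-identical pass-through);
whether photometric variants should also be generated per rotated copy is
unspecified in practice — this package expands one operator at a time,
which keeps the expansion factor linear and every variant attributable to
one operator.

## Patient-level folds and COCO synthesis

All slices of one subject share anatomy, noise and acquisition parameters;
splitting them across train and test would leak information and inflate
metrics. Fold construction therefore shuffles *subjects* (seeded) and
assigns them round-robin to $k = 5$ folds, so fold sizes differ by at most
one — 161 aneurysmal subjects give folds of 33/32/32/32/32. Healthy
(lesion-free) subjects never enter the rotation: they are appended to every
training split as background-only negatives, which is how the detector
learns to suppress false positives on normal vasculature, and they never
appear in validation splits. Disjointness of every train/validation subject
pair is asserted programmatically on each build.

Per fold, two COCO JSON files are emitted (`dataset_fold<f>_{train,val}.json`).
Annotations are per 8-connected mask component: tight 0-based
`[x, y, w, h]` boxes, pixel-count areas, and a segmentation in one of two
encodings:

* **bitmask** (default): uncompressed column-major RLE, lossless including
  interior holes — the encoding used for training;
* **polygon**: the outer boundary traced over pixel *corners*
  (half-integer coordinates). Because pixel centers sit at integers, no
  center ever lies on a polygon edge and even-odd rasterization
  reconstructs hole-free components exactly; holes are filled by
  construction, which is acceptable for solid blob lesions and is why the
  bitmask is the default where exactness matters.

Slices of aneurysmal subjects whose masks are empty (the lesion spans few
slices) are kept as additional negative images.

## Small-object-aware post-processing

The core post-processing logic computes, for every proposal, its physical
bounding-box area $w \cdot h \cdot s_x s_y$ in mm² from the header spacing
— never an assumed spacing. Proposals with area strictly below **28 mm²**
are candidate small aneurysms; the threshold sits inside the 25-35 mm²
band where standard score filtering and NMS were observed to suppress
small boxes. Two confidence thresholds then apply:

* ordinary proposals must clear the base threshold (default **0.9457**,
  the tuned inference threshold; a `"baseline"` preset carries the
  pre-tuning 0.90);
* small proposals need only **0.60**, countering the ROI classifier's bias
  toward large structures.

Since the small threshold never exceeds the base one, filtering can only
*add* proposals relative to a uniform base cut — small-object rescue never
removes anything, a property the test suite checks against a brute-force
oracle. The two stated base values (0.90 in the procedure description,
0.9457 in the tuned configuration) are not reconciled in the source
material; this package treats 0.9457 as the operative default and keeps
0.90 as a named preset. Small proposals additionally receive an advisory
pooling directive — FPN levels P2-P3, ROI pooling 14×14 — consumed by the
backend adapter.

For evaluation, lesions are grouped by physical size via the equivalent
diameter $d = 2\sqrt{A/\pi}$ of the in-plane mask area: **small** $d < 3$
mm, **medium** $3 \le d \le 5$ mm, **large** $d > 5$ mm (a
detection-difficulty grouping, not the clinical rupture-risk convention).
For 3D lesions the slice of maximal component area is measured — the mm
measurement protocol is otherwise unspecified, and this choice is
deterministic and reproducible. Boundary conventions are strict: exactly
28 mm² is not small; $d = 5$ mm is medium.

## Detector configuration and backend contract

The tuned training configuration ships as a typed object
(`default_config()`): base learning rate 0.00110 decaying ×0.1 at
iterations 4000 and 5500 over 6212 iterations, inference score threshold
0.9457, RPN NMS 0.5203, anchors 8/16/32/64/128 px with aspect ratios
0.5/1.0/1.5, RPN IoU thresholds 0.3/0.7, 512 RPN proposals per image at
positive fraction 0.5, ROI-head batch 256, bitmask mask format. The RPN
batch (512) and ROI-head batch (256) are distinct fields carried under
their own names. It serializes to flat upstream-style YAML
(`BASE_LR: 0.0011`, ...) with validation that names the offending key.

Actual GPU training is out of scope by design: `mock_backend()` satisfies
the adapter contract (`train(files, config) -> handle`;
`predict(slice_ref, handle) -> proposals`) from a scripted manifest, so the
dataset builder, filter and evaluator are exercised end to end without a
deep-learning framework. AMP and pretrained-weight tags are opaque
metadata.

## Evaluation

Metrics are **pixel-level**: TP/FP/FN pixel counts accumulated over slices,
then precision, recall, F1 and Dice as percentages. At pixel level F1 and
Dice are the same quantity algebraically — which is exactly why per-fold
reports print identical F1 and Dice columns — and the suite fuzz-tests the
identity to machine precision. Cross-validation summaries are unweighted
arithmetic means over folds, computed in full precision and rounded
half-up to two decimals only at report time. Undefined metrics (empty
denominators) report as `n/a`, never 0 or 100.

Size stratification assigns each ground-truth component's pixels to its
own size category; false-positive pixels are attributed to the category of
the *predicted* component's size (how else to blame a small spurious blob
on the small category?). This attribution rule is underdetermined in the
source material; the package's rule keeps per-category TP summing exactly
to whole-set TP.

## Synthetic phantoms

The generator emulates what the pipeline logic depends on — geometry and
contrast — not MR physics. Vessels are bright tubes (random-walk
centerlines along the slice axis, 0.8 mm radius); lesions are solid
hyperintense balls of controlled physical diameter seeded on a vessel
wall; the ground-truth mask contains lesions only. Defaults: 96×96×48
voxels at 0.5×0.5×0.8 mm, background/vessel/lesion intensities 40/320/400
arbitrary units, additive Gaussian noise σ = 10 applied before
normalization so the rescale sees realistic dynamic range. A cohort of 10
aneurysmal and 5 healthy subjects (the desk-scale mirror of a 161/286
clinical cohort) builds in a few seconds.

Cohort lesion diameters are drawn from category bands (≈2, ≈4, ≈6 mm) kept
clear of the 3/5 mm boundaries so rasterization noise cannot flip a
lesion's expected category; allocation across categories is deterministic
largest-remainder. Spheres, not saccular shapes: every decision the
package makes depends on scale, not morphology. Passing tests on phantoms
demonstrates the correctness of the plumbing and the post-processing
rules; they say nothing about detection performance on clinical TOF-MRA,
which requires a trained detector and real data.

## Worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(tempfile("demo"), n_aneurysmal = 10, n_healthy = 5,
                    k = 5, seed = 1)
metrics_table(res$fold_metrics, add_mean = TRUE)
metrics_table(res$size_metrics)
```

With the scripted mock detector (imperfect by construction: 1-pixel
localization jitter and depressed small-lesion confidences), seed 1 yields
a mean Dice near 76% with small-lesion recall around 62% — reproducing the
qualitative signature of size-stratified evaluation, where small lesions
trail large ones in recall.

## Numerical choices and limitations

* Rotation resamples with a backward map; its center convention
  (`(n-1)/2`, 0-based) makes 90° rotations exact on odd-sized frames.
* Polygon tracing resolves pinch points (diagonal 8-connected contacts) by
  preferring the left turn, keeping both lobes on one outer loop.
* Fold balancing is by subject count only, not lesion count or size.
* No DICOM, no registration or bias-field correction, no 3D merging of
  per-slice detections, no subject-level ROC (undefined under a slice-wise
  paradigm), no multi-class support.
* Problem sizes in the tests (48-96 voxel grids, 15-subject cohorts) are
  the package's chosen desk scale; all physical thresholds are
  scale-independent.
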