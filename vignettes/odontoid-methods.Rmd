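---
title: "OdontoID: models, parameters, and design choices"
author: "OdontoID maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OdontoID: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Forensic odontology identifies unknown deceased individuals by comparing
postmortem dental imagery against antemortem records. OdontoID implements a
computer-vision variant of that workflow for panoramic dental radiographs
(orthopantomograms, OPGs): antemortem images are reduced to keypoint
descriptors and stored — descriptors and acquisition ages only, never
pixels, so stored records cannot be inverted back to an image — and a
postmortem query is identified by geometric-verified descriptor matching
against the database. Because matching cost grows linearly with the
database, a convolutional network estimates the subject's age from the
query image and the search is restricted and ordered by the absolute
difference between entry age and that estimate.

The package is organized as the pipeline is: `preprocessRadiograph()` →
`extractFeatures()` → `FeatureDatabase` / `addEntry()` →
`scorePair()`/`rankCandidates()` → `predictAge()` → `identify()`.

## Preprocessing

Every image passes through a fixed, fully deterministic chain:

1. **Depth normalization** to 8 bits by linear rescaling of the declared
   range, `v -> round(v * 255 / (2^b - 1))`. Rescaling by declared depth
   (not per-image min–max) keeps the map independent of outlier pixels and
   identical across acquisitions.
2. **Margin crop** to a 180 mm × 100 mm field of view, centered, using the
   pixel spacing when present. Without spacing metadata a symmetric
   fractional crop (default 5% per side) stands in; crop anchoring is a
   package choice — nothing in the problem fixes it — and centered is the
   least surprising.
3. **Directional edge enhancement**: the image is correlated with the
   eight compass Sobel kernels (the standard `[[-1,0,1],[-2,0,2],[-1,0,1]]`
   operator with its border coefficients rotated clockwise in 45° steps),
   each signed response is multiplied by the edge gain 1.8, and the
   pixel-wise maximum over the eight orientations is clipped to `[0, 255]`.
   Two readings of "modulated with a parameter of 1.8" were possible
   (multiplicative gain vs. gamma); the multiplicative gain is implemented
   and the config records it as `edgeGainMode` so the alternative could be
   added without changing the contract. Taking the max of *signed*
   responses over all eight orientations equals the max absolute response
   up to the sign convention, since the kernel family contains every
   negated member.
4. **Noise reduction** with a 6×6 averaging filter. An even-sized box has
   no central pixel; the window is anchored at the top-left pixel of its
   center 2×2 block, which the impulse-response tests pin down exactly.

All filters use replicate (clamp-to-edge) padding, and pixel quantization
everywhere uses `floor(x + 0.5)` — half-away-from-zero — rather than R's
banker's rounding, so grids are platform-stable and the hand-computed
oracles in the tests are exact.

## Feature extraction

No AKAZE implementation exists in this R stack, so the package carries its
own KAZE-family extractor (`src/scalespace.cpp`): a Perona–Malik
nonlinear-diffusion scale space (conductivities PM_G1, PM_G2 — the
default —, Weickert, Charbonnier; contrast parameter at the 70th
percentile of gradient magnitudes; explicit time stepping with `dt = 0.2`)
organized in octaves that decimate the grid by two, five sublevels per
octave, and default eight octaves (internally capped once an octave drops
below 16 px). Keypoints are maxima of the scale-normalized
determinant-of-Hessian response under 3×3×3 non-maximum suppression above
`detectorThreshold` (default 1e-4 on `[0, 1]`-scaled intensities, chosen
once during development to yield a few hundred keypoints on synthetic
OPGs). Descriptors are upright M-SURF-style 64-vectors: a 20s × 20s window
sampled at spacing s, 4×4 subregions accumulating Gaussian-weighted
`(dx, dy, |dx|, |dy|)`, normalized to unit length. Upright (no orientation
assignment) is deliberate: radiographs have a canonical orientation.
Descriptors are quantized once to 32-bit float precision at extraction so
that serialization — little-endian float32 per the blob format — round-trips
bit-exactly.

`maxKeypoints` (default 300) keeps the strongest detections; a bounded
per-image budget makes database-scale matching cost predictable, as
production identification systems do. Subpixel keypoint refinement is
omitted — matching uses a 3 px reprojection tolerance, far coarser than the
half-pixel bias refinement would remove.

## Matching

Correspondences are exhaustive nearest-neighbour matches in Euclidean
descriptor space filtered by Lowe's ratio test at 0.7, made one-to-one on
the candidate side (closest pair wins; the "unique matching points" reading
of the original description). Geometric verification fits a homography
(config: also affine or similarity) with seeded RANSAC — normalized 4-point
DLT, 3 px transfer-error threshold, confidence 0.995, adaptive iteration
bound capped at 250, degenerate (collinear) samples rejected, one
least-squares refit on the best inlier set. The score between two images is
the inlier count; matching runs in both directions with the same seed and
the two counts are averaged, so the average is symmetric under argument
swap. Fractional averages (x.5) are kept as reals and ranking compares
reals, ties broken by ascending entry id for reproducibility.

A note on the ratio test with a single candidate keypoint: with no second
neighbour the test is vacuous and the pair is kept; `minCorrespondences`
(default 4) still gates scoring.

## Feature database

`FeatureDatabase` is an embedded, in-memory store with single-file
persistence, a schema version, and reference semantics (`addEntry()`
mutates, like any database handle). There is no SQL engine in this
environment; the relational design is kept at the contract level: one entry
table (id, individual, age at acquisition, serialized features, source
tag), an age ordering for radius queries, blobs validated on insert. Ages
are stored as reals — integer-year labels are the common case but nothing
downstream needs them integral. Whether to index age at acquisition or age
at search time is genuinely open; acquisition age is stored and the caller
supplies the search center, which keeps the store policy-free.

## Age regression CNN

The architecture follows the reference design: four blocks of three
convolution (3×3, same padding) + batch-normalization pairs with 32, 64,
128, 256 filters, each block closed by 2×2 max pooling and dropout 0.25;
flatten; a 1024-unit dense layer with batch normalization and dropout; one
linear output unit. Adam (lr 1e-4, batch 64) on mean-squared error, MAE as
the tracked metric, input 256×256 grayscale scaled to `[0, 1]` (min–max by
declared bit depth; per-image standardization was the other candidate and
is deliberately not used — it would discard the brightness cues that carry
age information in radiographs). The architecture text names no hidden
activations; ReLU after every batch-norm is the field's default and a
linear-only stack would collapse, so ReLU layers appear explicitly in the
manifest with zero parameters. Dropout sits after pooling, matching the
stated block order.

There is no deep-learning framework in this stack, so the network is
implemented natively: im2col + GEMM convolutions with full backpropagation
(Rcpp/Armadillo kernels, R orchestration), batch normalization with batch
statistics in training and running statistics (momentum 0.99, epsilon
1e-3) at inference, inverted dropout, Keras-compatible Adam defaults, and
glorot-uniform initialization. The gradient engine is verified against
central finite differences in the test suite.

Training follows the stated protocol: a fixed 80/20 train/validation split
made once from the plan seed; every 10 epochs each partition is reshuffled
internally (no sample ever migrates — asserted by the returned split);
augmentation on training batches only (rotation ±1°, width shift ±10%,
height shift ±20%, zoom factors in `[0.8, 1.2]` per axis, horizontal flip
with probability 0.5, nearest-edge fill — the usual reading of the "0–x%"
augmentation dialect); checkpointing keeps the epoch with minimal
validation MAE. Validation batches are not augmented; whether the original
protocol did is unstated, and not augmenting gives the cleaner model
selection signal.

One practical addition matters at desk scale: the output unit's bias is
initialized to the mean training age (`TrainPlan(initOutputBias = TRUE)`,
default). Adam's effectively bounded per-step update cannot move
predictions from zero to the ~45-year target scale within a few hundred
updates; starting from the best constant predictor removes that dead time
and is harmless for long runs.

### Profiles and problem sizes

The full-size profile (256×256, 32–256 filters, 1024 dense, 2500 epochs)
matches the reference design and is what `AgeCnnConfig()` builds. The
package's own experiments and tests run `ageCnnTestProfile()`: 64×64
input, blocks 8/16/32/64, 64 dense units, batch 16, lr 1e-3, batch-norm
momentum 0.9, trained for 30 epochs on 600 synthetic images with 120
held out. Those sizes keep a full training run in minutes on one CPU while
leaving the layer structure identical; the structural checks (manifest,
parameter count) cover the full-size configuration directly. The matching
and search experiments run on two fixture scales: a 20-individual database
(one enrolled render and one held-out query per individual) at the default
300-keypoint budget for end-to-end identification, and a 200-entry
age-spread database with 50 queries at a 200-keypoint budget for the
exhaustive-versus-gated search comparisons, where the brute-force oracle
dominates cost.

## Age-gated search

`identify()` composes the pipeline. Candidates are always visited in
ascending `|entry age − estimated age|` (ties by entry id): for fixed-radius
policies the order is harmless to the final ranking and lets early stopping
bite sooner; for the expanding policy it is the algorithm. The expanding
schedule (default ±5, ±10, ±15, ∞) widens until the database is exhausted;
scores are cached so no entry is ever scored twice (`matchCallCount()`
verifies ≤ 2 scoring calls per row). Early stopping fires when the best
average score reaches `earlyStopThreshold`. "Significantly higher than
impostor scores" is not a number anywhere in the problem statement, so the
threshold is explicit policy, with `calibrateEarlyStop()` — impostor mean +
5 SD — as the calibration utility kept separate from the search itself.
Because elderly subjects tend to be estimated younger than they are, the
policy can widen the younger-side radius (factor 1.5 above estimated age
70); it is opt-in because it trades extra comparisons for recall. Only the
CNN estimate ever enters the gate — true ages never leak into the search
path.

## The synthetic-radiograph generator

Clinical OPGs cannot be shared, so every empirical test in this package
runs on `makeCohort()` / `renderOpg()` output. The generator is explicitly
*not* anatomically realistic; it reproduces the two statistical properties
the pipeline needs:

* **Identity-stable structure.** A structure seed fixes the dental-arch
  curve, per-tooth slot jitter, widths, brightness, and two intra-tooth
  texture spots per tooth (a fillings analogue). Repeat acquisitions of one
  individual differ only by acquisition jitter; different individuals get
  different geometry, so descriptor sets separate cleanly.
* **Age-monotone appearance.** Tooth count ramps from the deciduous 20 to
  the full 32 over ages 2–21 (eruption analogue); crown height shrinks 30%
  and pulp-core brightness 60% linearly over ages 21–89 (attrition and
  pulp-narrowing analogues); background trabecular texture coarsens with
  age. These give the CNN a recoverable, monotone signal.

Acquisition defaults — noise SD 2 (8-bit units), positioning rotation
within ±0.7°, shifts within ±2.5 px, gamma in `[0.95, 1.05]`, render
220×400 px at 0.5 mm/px, and occlusion rectangles covering ~5% of query
(postmortem-style) images only — were chosen once as plausible clinical
jitter. Ages are uniform on [2, 89], the range the reference model was
trained for. Cohorts destined for CNN training (`renderCohortImages()`)
draw their occlusion fraction uniformly over `[0, 0.05]`, so the estimator
trains on the same acquisition distribution its queries come from — the
deliberate "no filtering" stance of the reference workflow. Occlusion is a
harsh degradation at 64×64: a rectangle landing on the dental arch removes
most of the age signal of a render, which is why a small fraction of
age estimates on degraded queries still miss by more than ten years; the
expanding-radius schedule and early stopping exist precisely to make such
misses cost time rather than identifications.

What passing tests therefore show: the pipeline separates genuine from
impostor comparisons, the age gate preserves identification while pruning
most of the database, and the CNN recovers a monotone age signal — all
*under the generator's assumptions*. What they cannot show: performance on
clinical radiographs, whose identity cues (restorations, root morphology,
sinus outlines) and age signal are far richer and noisier than the
generator's analogues.

## Numerical choices and degenerate inputs

* Half-away-from-zero rounding for all pixel quantization.
* Replicate padding for image filters; zero padding inside CNN
  convolutions (the Keras convention for `padding = "same"`).
* Empty keypoint sets propagate as score 0, never as errors; extraction of
  a structureless image warns and returns an empty set.
* RANSAC with fewer points than the minimal sample returns 0; degenerate
  (collinear) minimal samples are skipped.
* Database ties (equal `|Δage|`, equal average score) always break by
  ascending entry id.
* All randomness (RANSAC, augmentation, dropout, splits, cohorts) derives
  from explicit integer seeds via one multiplicative-congruential
  derivation, so every result in the tests and the acceptance script is
  exactly reproducible.

## Known limitations

* The extractor is KAZE-family but not byte-compatible with any OpenCV
  AKAZE build (no FED time stepping, no subpixel refinement, M-SURF
  descriptor only); its configuration surface and invariants match, and
  within this package that is the contract that matters.
* The feature store is in-memory with file persistence; at the reference
  scale (10^5 entries) a disk-backed engine would be the right backend
  behind the same API.
* The full-size CNN profile is buildable and trainable but a 2500-epoch,
  50,000-image run is outside desk scale; empirical claims in this package
  are made for the test profile on synthetic cohorts only.
* Sex differences are not simulated (none were significant in the
  reference data) and DICOM ingestion is out of scope.
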