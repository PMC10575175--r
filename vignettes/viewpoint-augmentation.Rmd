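---
title: "Viewpoint-augmented skeleton action recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viewpoint-augmented skeleton action recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Recognising a martial-arts technique from video depends, uncomfortably, on
where the camera stands: a model trained on frontal recordings degrades badly
on oblique views.  When the training data are 3D skeletons from a
motion-capture suit, there is a cheap escape: a 3D skeleton can be projected
through a *virtual* camera placed anywhere, so 2D training data from any
viewpoint can be synthesized at will.  `viewact` implements that pipeline end
to end:

1. 3D skeleton clips (16 joints per frame, metres) are projected through a
   pinhole camera that orbits the subject, yielding 2D skeletons at chosen
   angles;
2. each 2D clip is rendered into a `T x H x W` Gaussian heatmap volume
   (joint maps or bone maps);
3. a compact two-pathway (slow/fast) 3D CNN is trained on the volumes with
   SGD and cross-entropy;
4. a viewpoint-generalization experiment compares classifiers trained on 2,
   4, 8 and 36 projection angles, evaluated on held-out subjects projected
   over a dense 10-degree grid.

Because the motion-capture corpus that motivates the design is not publicly
available, the package carries a synthetic-motion generator that reproduces
the corpus's *structure* — subjects x actions x repetitions, class-distinct
kinematics, inter-subject variability, sensor noise — without pretending to
reproduce Taekwondo biomechanics.

## The synthetic-motion generator

Each action class is a fixed *limb program*: a class-specific subset of 4-6
bones, each swung about a fixed class-specific axis by a sinusoidal joint
angle with its own amplitude (0.35-0.9 rad), frequency (0.5-1.8 Hz) and
phase, layered on a standing rest pose, plus a small lateral sway of the
pelvis.  Motion is produced by forward kinematics — each bone's rest offset
is rotated by its per-frame angle (Rodrigues' formula) and positions
accumulate down the tree — so noiseless bone lengths are constant over time
by construction, as rigid-body motion demands.  Subjects contribute a fixed
limb-length scale (uniform in 0.92-1.08) and speed factor (1 +/- 0.1);
repetitions differ by phase offsets; isotropic Gaussian noise (default
0.01 m, the order of an IMU-suit's positional error) models the sensor.

Seeding is hierarchical: class programs depend only on the class index, so
class k means the same motion in every dataset; subject factors and per-clip
jitter derive from the dataset seed by a counter-based splitting function, so
datasets are bit-reproducible and clips are independent of generation order.

The default corpus is 6 subjects x 16 actions x 3 repetitions, 48 frames at
24 Hz — deliberately small, so the full experiment runs on one CPU in
minutes; the full-scale structure (40 x 16 x 12 = 7680 clips) is a
configuration away and is exercised for its count structure by the test
suite.  What passing tests on this corpus show is that the *pipeline* learns
and that viewpoint diversity pays off on separable spatiotemporal classes;
they say nothing about real martial-arts data, where classes overlap,
execution varies far more, and pose estimators add structured noise.

`class_separability_check()` guards the generator: a leave-one-out 1-NN
classifier on per-joint coordinate variances must reach accuracy 1.0 on
noiseless output (it does), degrade monotonically with noise, and collapse
to chance under label permutation.

## Camera orbit and projection

The camera circles the subject on a horizontal orbit about the vertical axis
through the orbit centre (by default the clip's median pelvis position): the
position at angle theta is the angle-0 position — centre + (0, -radius,
height) — rotated about that axis, always aimed at the centre.  Projection
is a standard pinhole: `P = K [R | t]` with equal focal lengths, zero skew,
principal point at the image centre, applied in homogeneous coordinates with
an explicit perspective divide.  Pixel convention: origin top-left, x right,
y down, continuous 0-based coordinates.

Defaults (declared, since no reference values exist): orbit radius 3 m,
camera at pelvis height (`height = 0` relative to the orbit centre), focal
length set so a 2.2 m figure at 3 m fills ~80% of the image height.  Points
at or behind the camera plane raise an error naming the frame and joint —
with this geometry they always indicate misconfiguration, so silent clipping
would hide bugs.

Two properties pin the implementation down numerically: rotating the camera
by theta must equal counter-rotating the skeleton by -theta (verified to
1e-6 over the full 36-angle sweep), and projection must agree with an
independently coded world-to-camera/divide/intrinsics oracle to 1e-9.

## Heatmap volumes

For one frame with joints `u_k`, pixel `(i, j)` of the joint map holds
`sum_k exp(-D(i,j,u_k)^2 / sigma^2)`; the bone map replaces the distance by
the shortest distance to each bone segment.  Two choices deserve comment:

* the exponent's denominator is `sigma^2`, not `2 sigma^2` — the map is the
  kernel in its printed form rather than a normal density (a consequence is
  that a single joint's mass tends to `pi sigma^2`, which the tests confirm
  to 2%);
* overlapping contributions are *summed*, not maximised, so crossing limbs
  brighten.

Both are switchable (`denominator`, `accumulate` in `heatmap_config()`)
because the related literature often uses the other convention; the defaults
follow the form above.  There is no clamping or per-frame normalisation: the
classifier's instance normalisation makes global scale irrelevant.

Before rendering, each clip is cropped to the minimal bounding box enclosing
*all* joints over *all* frames (the subject moves within a confined area, so
a per-clip box keeps the motion trajectory intact), padded by 10% per side,
and mapped onto the output grid with one uniform scale (aspect preserved,
letterboxed).  The temporal axis is reduced by uniform sampling: `[0, T_in)`
is split into `T_out` equal bins and one frame is taken per bin — the bin
centre for evaluation (deterministic), a seeded uniform draw within the bin
for training augmentation.  Rendering defaults are sigma 1.5 px on a
64 x 64 x 12 volume; the experiment uses 24 x 24 x 8 (below).

## The classifier

The network has two pathways.  The slow pathway consumes every 4th frame at
full width (stem of `base_channels`); the fast pathway consumes every frame
at a fraction (default 1/8) of the width.  Each pathway is a 3D-conv stem
(3x3x3, spatial stride 2) followed by residual stages whose channels double
per stage; time-strided 3D convolutions (kernel and stride `slow_stride` in
time) carry fast features into the slow pathway after the stem and after
each non-final stage.  Global average pooling, feature concatenation and a
linear softmax head close the model.

Because no deep-learning framework is assumed, convolution
forward/backward are implemented as compiled im2col + GEMM kernels, and all
other gradients (instance normalisation, ReLU, residual adds, pooling,
softmax cross-entropy) are hand-chained in R.  The test suite contains a
finite-difference gradient check over every layer type; it is the test that
makes the rest of the training results trustworthy.  Instance normalisation
(per sample, per channel, affine) was chosen over batch normalisation
because training accumulates per-sample gradients, making the result
independent of batch composition and exactly reproducible.

Training is plain SGD with momentum 0.9, optional weight decay, seeded
shuffling; `slowfast()` returns a classed model object with `print`,
`summary`, `predict`, `plot` (loss curve) and `coef` methods.  Ties in the
argmax resolve to the lowest class index.

## The viewpoint experiment

Four training configurations are compared, named after their viewpoint
sets: A = {0, 90}, B = {0, 90, 180, 270}, C = the 45-degree grid (8 views),
D = the 10-degree grid (36 views).  Subjects are split disjointly (2 of the
6 held out by default; the full-scale analogue is 30/10); each model trains
on its own projections of the training subjects and is evaluated on the
held-out subjects projected over the full 10-degree grid, plus an "in-view"
score at its own training angles.  Metrics are per-class one-vs-rest
precision/recall/F1 with *macro* (unweighted) averaging — chosen because
per-class averaging is the only reading consistent with aggregate
precision/recall/F1 triples that are not harmonic-mean-consistent, as
reported in this literature — while accuracy is micro (correct/total).
Undefined ratios (empty denominator) score 0 and are flagged rather than
dropped.  Cross-validation folds, like the outer split, are subject-disjoint:
the claim under test is generalization to unseen performers, so folds that
share subjects would leak.

### Problem sizes and schedules

All sizes were fixed once, as the package's desk-scale defaults, and the
test suite runs them as-is: experiment volumes 24 x 24 x 8; experiment
network `base_channels = 8`, one residual block per stage, fast fraction
1/4 (about 25k parameters); 2 epochs for the experiment's heavily augmented
training sets (up to 36 views x 144 clips); 20 epochs for the 5-fold CV
sanity run; 50-epoch cap for the 8-volume overfit check.  The module-level
`slowfast_config()` default keeps the conventional ratios (base 16, two
stages of depth 2, fast fraction 1/8) for users scaling up.  With these
defaults one full A-D experiment takes roughly four minutes on a single
CPU core, and the expected qualitative result — accuracy increasing with
training-viewpoint density, D far ahead of A — is reproduced for every seed
tried; absolute accuracies are far below the high-nineties achievable at
full scale with long schedules, which is the accepted trade-off.

## Numerical and degenerate-input choices

* Crop: a clip whose joints all coincide (zero-area box over all frames) is
  an error; a box degenerate in one dimension only uses the other
  dimension's scale.
* Uniform sampling with `T_in < T_out` repeats bin-boundary indices, so the
  output length is always `T_out` and indices are non-decreasing.
* Softmax is computed with max-subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Instance normalisation uses epsilon 1e-5.
* The 1-NN separability check breaks distance ties towards the lowest clip
  index, making degenerate (all-identical) datasets deterministic.
* Seeds derived for sub-streams (clips, folds, experiment stages) use a
  fixed integer mixing function kept below 2^31.

## Known limitations

* The generator's classes are separable by per-joint variance alone; real
  unit actions are not, so absolute accuracies here do not transfer.
* Projection assumes an ideal pinhole: no lens distortion, no occlusion, no
  keypoint confidence; estimated 2D input is accepted (`read_keypoints_csv`)
  but must be complete per frame.
* The classifier trains sample-by-sample on CPU; it is sized for the
  package's experiments, not for GPU-scale replication.
* Single-person clips only; multi-person frames are out of scope.
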