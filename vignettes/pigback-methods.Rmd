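---
title: "Methods: hybrid point-cloud denoising and pig weight estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid point-cloud denoising and pig weight estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigback)
```

# The problem

A single depth camera mounted about 2.5 m above a weighing passage sees a
sow from directly overhead. The raw point cloud mixes the animal's back with
the floor, sparse sensor outliers hovering above and around the body
("large-scale" noise), and small dense clumps of spurious returns offset
from the body ("small-scale" noise). `pigback` turns such a cloud into six
back body-size features and a weight estimate, through a fixed sequence of
stages:

1. statistical k-NN outlier filter (large-scale noise),
2. DBSCAN density clustering plus elevation-based cluster selection
   (small-scale noise and floor/pig separation),
3. rigid horizontal alignment by the minimum-area bounding rectangle,
4. concave-outline sag analysis to cut off head and tail,
5. voxel-grid centroid downsampling,
6. convex-envelope and outline feature extraction,
7. CNN regression of body weight from a back height raster plus the feature
   vector (with an RBF network as baseline).

# Stage models and parameters

## Statistical outlier filter

For each point the mean Euclidean distance $\bar d_i$ to its $k$ nearest
other points is computed on a k-d tree (the query point is excluded: a
self-distance of zero would bias $\bar d_i$ downwards). With
$\mu = \operatorname{mean}_i \bar d_i$ and $s$ the sample standard deviation
(denominator $n-1$), a point is deleted iff $\bar d_i > L = \mu + \sigma s$.
Equality retains the point: the deletion rule is strict, and retaining is
the least destructive reading. Defaults $k = 30$, $\sigma = 2$. Equidistant
neighbours are ordered by point index, making results invariant to input
permutation.

## DBSCAN and pig-cluster selection

Classical DBSCAN with radius `eps` (default 0.02 m) and `min_pts`
(default 10; the $\varepsilon$-neighbourhood includes the point itself when
counted against `min_pts`). Cluster ids are assigned in scan order of the
point index; a point provisionally marked noise can later join a cluster as
a border point. The only permutation sensitivity is the documented one:
border points equidistantly reachable from two clusters follow scan order.

`min_pts` is not a reported parameter of the recording pipeline we emulate;
10 is a density-robust choice for clouds sampled at roughly 7 mm pitch,
where genuine surface points have dozens of neighbours within 2 cm.

The pig is then selected by *elevation*, not size: the floor is the largest
cluster in an overhead scene. Among clusters of at least `cluster_min_size`
points (default 100 — real noise clumps are tens of points, a pig is
thousands) whose mean height exceeds the floor level by `floor_margin`
(default 0.1 m), the highest-mean cluster wins. The floor level is the
modal height of the largest cluster when that cluster is flat, else the 1st
percentile of all heights.

## Alignment, outline and head/tail splitting

The minimum-area enclosing rectangle of the horizontal projection is found
over convex-hull edge orientations (its optimum provably lies on a hull
edge) and the cloud is rotated about $z$ so the rectangle is axis-parallel
with the long side along $x$. The rotation is rigid; the angle is reported
in $(-90^\circ, 90^\circ]$.

The 2D outline is an alpha-shape boundary: an edge between points at most
$2\alpha$ apart is on the boundary when one of the two radius-$\alpha$
disks through them is empty. $\alpha$ defaults to three times the median
nearest-neighbour spacing — small enough to follow the neck and tail
notches, large enough to bridge sampling gaps. The implication worth
knowing: concavities sharper than $\alpha$ are smoothed, so split points on
a geometrically sharp notch land within a few samples of the true tip, not
on it.

Sag is the perpendicular distance from each outline vertex to the hull edge
spanning it. Split candidates are sag local maxima at least `sag_min`
(default 0.03 m — deeper than outline roughness at 7 mm sampling, shallower
than any real neck crease) deep. With the head direction fixed (flag,
default `+x`), the tail cut is the candidate farthest from the centroid-x
axis on the tail side and the head cut the candidate nearest the axis on
the head side — the neck crease sits closer to the body centre than the
snout. A side with no candidate is left uncut with a warning; if both
candidates fall on one side, only that side is trimmed.

## Voxel downsampling

Cubic cells of side $r$ (default 0.005 m) anchored at the coordinate
minima, $D = \lceil (\max - \min)/r \rceil$ cells per axis, flat index
$h = h_x + h_y D_x + h_z D_x D_y$ with half-open cells and upper-boundary
clamping. Each occupied cell is replaced by its centroid, output sorted by
$h$ (hence permutation-invariant); the cell's majority label is carried,
ties becoming `unknown`. The achieved reduction depends on the cloud's
density relative to $r$ and is visible in the stage report; no fixed rate
is asserted.

## Back features

Six features per pig: 3D convex-envelope volume and surface area
(quickhull; signed-tetrahedron volume, triangle-sum area), shoelace area of
the concave outline (so head/tail trimming is reflected — the convex hull
area is separately available), and three widths. The width rule splits the
outline's $x$ range into equal thirds and takes the extremal-$y$ vertex
pair per third, anterior third mapping to shoulder, middle to belly,
posterior to hip. This thirds rule is a declared interpretation: the
measurement protocol we emulate names six outline keypoints without
defining them constructively, and anatomical sections at fixed fractions of
body length are the standard morphometric fallback. No ordering between
envelope area and projection area is asserted; they measure different
surfaces.

## Weight models

The CNN takes a 64x64 height raster of the trimmed back (cell = mean
height above the cloud minimum; empty cells 0) through
conv(8, 3x3) - pool - conv(16, 3x3) - pool, flattens, concatenates the six
features, and regresses through FC(64) to a single linear output. Pooling
is a learnable per-channel affine over a 2x2 mean pool
($\beta \cdot \text{down}(\chi) + B$), not a max pool, matching the
down-sampling layer definition this package implements. Activations are
ReLU. Inputs (raster globally, features per column) and the target are
z-scored and restored at prediction.

Training is plain full-batch gradient descent on the mean squared error:
learning rate 0.005, 300 epochs. The rate is the stable choice for this
architecture — 0.03 diverges with the conv stack — and 300 epochs bring the
training loss into its flat regime at this problem size. Loss history is
recorded; monotone descent is not guaranteed (plain GD) but the final loss
must fall below the initial one on all fixtures. A features-only mode
(`conv = list()`) gives the ablation without the raster path.

The RBF baseline uses Gaussian hidden units centred on a seeded sample of
training feature vectors, width equal to the median pairwise centre
distance, and least-squares output weights (ridge fallback with a warning
when singular).

Metrics: MAE $= \frac1N\sum|P_k - R_k|$, MAPE
$= \frac{100}N\sum|P_k - R_k|/R_k$, RMSE
$= \sqrt{\frac1N\sum(P_k - R_k)^2}$. RMSE $\ge$ MAE always (power-mean
inequality); MAPE is undefined for a zero actual weight and errors out.

# The synthetic scene generator

Real recordings of this kind (hundreds of sows, thousands of clouds) are
not publicly deposited, so every stage is validated on simulated scenes
with known labels and weights.

A scene is a single overhead *heightfield* sampled on the camera grid —
exactly what one depth camera produces, one return per ground-plane pixel:

* floor patch 2.5 m x 1.7 m at $z = 0$ (the 1.7 m passage width across the
  body axis), sampled at 7 mm pitch, occluded beneath the body;
* torso: upper superellipsoidal shell
  $z = 0.6H + 0.4H\sqrt{1 - (x/a)^4 - (y/b)^2}$ with $a = L/2$, $b = W/2$
  and apex $H$ — blunt-ended like a real pig barrel, visible down to a 0.6H
  "equator" as seen from above;
* head: a raised half-ellipsoid overlapping the $+x$ torso end (apex
  $0.72H$, width $0.42\,W$, protruding 0.25 m), tail: a thin one at $-x$
  (protruding 0.12 m). Both overlap the torso so the visible surface steps
  down smoothly across the seams (steps well under the DBSCAN radius), and
  both pinch the planar outline into concave neck/tail notches several
  centimetres deep;
* samples on surfaces steeper than 75 degrees are dropped — depth cameras
  lose returns at grazing incidence, and this dropout is what keeps the
  simulated rim from producing an unrealistically sparse halo;
* Gaussian coordinate jitter (sd 3 mm) on all surface returns;
* large-scale noise: 300 points uniform in the body bounding box dilated by
  0.3 m, rejected within 5 x pitch of any surface point (a measurable
  separation so the filter stage has an unambiguous target);
* small-scale noise: 5 Gaussian blobs of 40 points (sd 1 cm) centred at
  least 0.1 m from the body.

Body dimensions are drawn uniformly from 1.5-1.9 m length, 0.45-0.60 m
width, 0.50-0.65 m height. True weight follows the allometric power law
$W = c_w (LWH)^{b_w}$ with $b_w \approx 0.581$, $c_w \approx 356.9$,
calibrated so the smallest and largest dimension configurations map exactly
onto the 190-300 kg herd range (a single linear coefficient cannot satisfy
both endpoints — the volume ratio across the ranges is 2.20 while the
weight ratio is 1.58 — and a power law in body volume is the canonical
allometric form). Multiplicative Gaussian noise with CV 0.03 models
scale-reading and condition variability; with CV 0 the weight is an exact
function of the dimensions.

What the generator does *not* emulate: posture variation, occlusion by pen
fixtures, realistic depth-sensor noise spectra, and partial views. Passing
tests therefore demonstrate that the pipeline recovers what it claims under
an idealised but fully specified overhead-scene model — not field accuracy
on farm data.

# Numerical choices and degenerate inputs

* k-NN and region queries break distance ties by point index; all stage
  outputs are permutation-invariant up to the documented DBSCAN border
  exception.
* The minimum-rectangle search treats area ties within a $10^{-12}$
  relative band as equal and keeps the first optimum; the alignment angle
  is normalised to $(-90^\circ, 90^\circ]$.
* Quickhull uses a relative tolerance of $10^{-10}$ times the cloud extent
  for visibility tests; coincident, collinear and coplanar inputs are
  rejected with specific errors.
* The alpha outline errors out (suggesting a larger alpha) when the
  boundary does not close or when the closed loop contains fewer than 99%
  of the points.
* Voxel cells are half-open with upper-boundary clamping, so points on the
  exact maximum plane stay in the last cell.
* PLY output is written as float64 in both dialects, so write-read round
  trips are bit-exact; big-endian input is rejected.
* Standardisation guards: any zero standard deviation is replaced by 1
  before z-scoring.

# Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from code:
unit fixtures are at most a few thousand points; oracle equivalences run on
random clouds up to n = 500 (filter) and n = 300 (DBSCAN); segmentation
recovery uses five full default scenes (~87,000 points each); and the
weight-estimation check simulates 198 pigs, trains on 140 and evaluates on
the held-out 58 — the herd size and split of the recording campaign this
package models, reproduced at one cloud per pig. Replicating several clouds
per animal, as a recording campaign would, is a config choice
(`generate_herd` with repeated seeds), not exercised by default.

# Known limitations

* The head/tail split assumes a known head direction; scenes with the head
  at $-x$ must set the flag.
* Split cuts are axis-perpendicular planes; an obliquely standing pig is
  handled only insofar as the rigid alignment straightens it.
* The alpha-shape outline smooths concavities sharper than $\alpha$, so
  split coordinates carry an $O(\alpha)$ bias toward the body on very sharp
  notches.
* The CNN is a small fixed architecture trained by plain gradient descent;
  it is adequate for the simulated allometric relationship (test MAPE well
  inside the single digits) but no claim is made about field data, posture
  robustness, or transfer across breeds.
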