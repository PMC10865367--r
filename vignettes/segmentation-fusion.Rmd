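---
title: "Fusing multiple 2D segmentations into a consensus contour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multiple 2D segmentations into a consensus contour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segfuse)
```

## The problem

Drawing the boundary of an object in an image — a tumor area in a
histological section, a cell in a light-sheet microscopy stack — is
subjective. Different annotators produce different closed lines for the same
object, and the same annotator disagrees with themselves across sessions.
When several segmentations of the same object are available (from several
experts, or from several automatic tools), a natural way to mitigate this
inter- and intra-rater variability is to *fuse* them into a single consensus
contour. There is no validated, universally best fusion rule, which is why
this package implements a catalogue of eight algorithms rather than a single
one, together with the machinery to compare them on a common benchmark.

All inputs are binary masks of identical size: the object is the foreground,
drawn either as a filled region or as a closed line possibly thicker than
one pixel. The output is always a closed, one-pixel-wide contour line.

## Conventions

* Masks are logical matrices indexed `[row, col]`, 1-based, row 1 at the
  top. Angles are measured counterclockwise from the +column axis.
* Foreground is 8-connected, background 4-connected. This standard dual
  pair prevents background from "leaking" diagonally through a one-pixel
  line while letting diagonal steps of a contour count as closed.
* Hole filling converts background pixels not 4-connected to the image
  border into foreground.
* A contour line is *closed* when it encloses at least one background
  pixel, and *one-pixel wide* when topology-preserving (Zhang–Suen)
  thinning leaves it unchanged.

## From a mask to a one-pixel line

A drawn boundary thicker than one pixel can be reduced to a one-pixel line
in three ways (`extract_line()`):

* **internal** — foreground pixels of the hole-filled mask with a
  4-neighbour in the background;
* **external** — background pixels 4-adjacent to the hole-filled mask;
* **middle** — the skeleton of the original (unfilled) thick line:
  Zhang–Suen thinning followed by iterative removal of endpoint pixels
  (spur pruning) until only the closed loop remains. On a filled blob, where
  "middle of the line" is undefined, the mode falls back to internal with a
  warning.

The default mode is **external**, matching the tool's default
configuration. Note that filling an external contour yields the region
*plus* its one-pixel ring; when contours are scored against raw regions
(see *Evaluation* below) this inflates every area slightly, which is why
the package's own benchmarks evaluate with the internal line.

## Closing sparse contour points

The averaging fusion algorithms emit isolated consensus pixels. To connect
them, each pixel needs at least two neighbours, which are hard to identify
in the Cartesian plane; the points are therefore converted to polar
coordinates about a common centre (the centroid of the filled union of the
input segmentations) and ordered by angle, after which the radius is a
function of the angle and neighbours are simply the angularly adjacent
points. This model assumes the contour is star-shaped about the centre;
strongly non-star-shaped point sets are accepted but only approximated.
Points whose angles collide within 1e-9 rad are merged by averaging their
radii, keeping `r(theta)` single-valued.

Four closing methods are available:

* **linear** (`close_linear()`): consecutive points (cyclically) are joined
  by rasterized straight segments, the two-point interpolant
  `f(x) = (x1-x)/(x1-x0) y0 + (x-x0)/(x1-x0) y1`.
* **pchip** (`close_pchip()`, the default): monotone piecewise-cubic
  Hermite interpolation of `r(theta)`, wrapped periodically (three samples
  are repeated on each side of the seam so it is interpolated with interior
  slopes). The interpolant passes through every sample and preserves
  monotonicity — no overshoot beyond the bracketing radii. The interpolant
  is only *evaluated* across gaps wider than about a pixel; points that are
  already adjacent are connected directly, so a dense input ring is
  retraced rather than resampled through a smooth curve.
* **chan_vese** and **geodesic** (`close_active_contour()`): morphological
  active contours initialized at the filled convex hull of the points. The
  energy image is built from the Euclidean distance transform `d` of the
  point set: Chan–Vese runs on a gap-closed, lightly blurred guide region,
  the geodesic method on the stopping function `g = 1 - 1/(1 + (d/2)^2)`
  (≈0 on the points, →1 away) with a shrinking balloon and stopping
  threshold 0.3. Defaults are 100 iterations and 1 smoothing pass.

Both interpolation closers guarantee that **every input pixel appears in
the output**: the final thinning pass never deletes an input pixel (a plain
thinning could remove a knot sitting on a staircase). The active-contour
closers do not offer this guarantee.

Rasterization uses integer Bresenham segments between consecutive curve
vertices; interpolated curves are sampled densely enough that consecutive
vertices are at most about half a pixel apart.

## The eight fusion algorithms

Let the inputs be `D_1 ... D_N` (after line extraction and hole filling).

* **Largest** — perimeter of the hole-filled union of all inputs: the
  segmentation containing all others.
* **Smallest** — the masks are hole-filled first, then summed; pixels whose
  count equals N form the common area, whose perimeter is returned. Empty
  intersection is an error.
* **Average Smallest And Largest** — the one-pixel line halfway between
  Smallest and Largest. The closed band between the two regions (the
  annulus plus both boundary rings) is skeletonized onto its equidistant
  midline, computed from the distance transforms as the boundary of
  `{d(p, S) <= d(p, outside L)}`. Iterative thinning is deliberately *not*
  used for this band: its convex outer boundary thins faster than its
  concave inner one, which biases the line inward by about a pixel on a
  circular annulus. When Smallest equals Largest the common perimeter is
  returned.
* **Average Target (Largest / Smallest / From Input)** — a target contour
  is chosen (the Largest, the Smallest, or the k-th input). For every pixel
  of the target, a group is formed with one member per input segmentation:
  the nearest pixel (Euclidean; ties broken by smallest row then column) of
  each other contour, plus the target pixel itself standing in for its own
  segmentation. The group's consensus point is the midpoint for two
  points; for more than two exactly collinear points (integer cross-product
  test — group members are grid pixels, so no tolerance is needed), the
  midpoint of the two mutually farthest points; otherwise the arithmetic
  mean. Exact polygon-area centroids were rejected because no polygon
  ordering is defined for a handful of unordered points. Consensus points
  are rounded half-away-from-zero to the grid and closed with the
  configured closing method.
* **Middle** — inputs are ranked by filled area ("size" is not defined by
  containment for crossing contours, so area is used; ties remove the
  lowest rater index). `floor((N-1)/2)` iterations each remove the current
  smallest and largest member. For odd N one survivor remains and its
  contour is returned bit-identically; for even N the two survivors are
  fused with the configured tiebreak (Average Smallest And Largest,
  Largest, or Smallest). With N = 2 and the average tiebreak, Middle
  reduces exactly to Average Smallest And Largest.
* **STAPLE** — binary expectation-maximization consensus
  (`staple_consensus()`). The hidden true segmentation `T` and each rater's
  sensitivity `p_j = P(D_j = 1 | T = 1)` and specificity
  `q_j = P(D_j = 0 | T = 0)` are estimated jointly. The reference is
  initialized by per-pixel majority vote and `(p_j, q_j)` estimated against
  it; the E-step computes the per-pixel posterior foreground weight

  `W_i = a_i / (a_i + b_i)`, with
  `a_i = pi * prod_j p_j^{d_ij} (1-p_j)^{1-d_ij}` and
  `b_i = (1-pi) * prod_j (1-q_j)^{d_ij} q_j^{1-d_ij}`

  (computed in log space); the M-step re-estimates
  `p_j = sum_i W_i d_ij / sum_i W_i` and
  `q_j = sum_i (1-W_i)(1-d_ij) / sum_i (1-W_i)`. The prior `pi` is the mean
  foreground fraction of the inputs, held fixed. Iteration stops when
  `max |dW| < tol` (default 1e-6), when the thresholded reference stops
  changing, or at `max_iter` (default 100, then a warning). The consensus
  region is `{W >= 0.5}`, hole-filled; if it splits into several components
  the largest is kept with a warning. Estimates are clamped to
  `[1e-6, 1 - 1e-6]` so unanimous raters do not produce degenerate
  likelihoods. All of STAPLE's controls are exposed in `fusion_config()`.

None of the algorithms is stochastic; only the synthetic module consumes
seeds. Largest, Smallest, Average Smallest And Largest, Middle (odd N) and
STAPLE are invariant under permutations of the input order.

New algorithms can be added at run time with `register_algorithm()`, with a
declarative parameter schema that the config-file layer validates.

## Evaluation

`jaccard()` implements `JI(A, B) = |A ∩ B| / |A ∪ B|`. Both inputs are
hole-filled before counting, so one-pixel contours are compared as the
regions they enclose — the raw pixel-set JI of two thin rings is near zero
regardless of how well they agree, and is not a useful boundary-agreement
score. `rank_algorithms()` runs a list of configurations over a list of
cases, fills the JI matrix, and ranks by descending mean; a fusion failure
leaves an `NA` cell that is excluded from that row's mean (zero-filling
would silently punish erroring algorithms).

The package's own benchmarks evaluate fused contours with
`line_mode = "internal"`, so that filling the fused contour recovers the
consensus region exactly and fused outputs are compared to raw rater masks
on an equal footing.

## The synthetic benchmark

`make_shape()` builds star-shaped ground truths (disks, ellipses, and
"blobs" whose radius is modulated by low-order harmonics) that must fit
their canvas with a 2-pixel margin so external rings never leave it.
`simulate_raters()` provides two disagreement models:

* **boundary raters** emulate inter-rater contour variability: the radius
  `r(theta)` of the truth about its centroid is displaced by a truncated
  Fourier series (default 3 harmonics) scaled so the maximum displacement
  equals the stated amplitude. The series includes the constant term, so a
  rater can be systematically biased outward or inward — the dominant
  effect seen between real annotators, and the one that outlier-removing
  algorithms (Middle, Average Smallest And Largest) are designed for; the
  bias is zero-mean across raters. With only wobble and no bias term, no
  rater is an outlier and area-ranking has nothing to remove.
* **bernoulli raters** implement exactly the generative model STAPLE
  assumes: each truth pixel is kept as foreground with probability `p`,
  each background pixel kept with probability `q`. The raw flip field is
  attached as `attr(, "raw")` so STAPLE's parameter recovery can be
  measured against the model it assumes; the returned masks additionally
  get a cleanup (largest component, hole filling) so they satisfy the
  single-object invariants. The cleanup raises the effective sensitivity
  (isolated interior misses are re-filled), so recovery checks use the raw
  fields.

What the simulator does **not** model: texture and intensity (masks only),
multi-object scenes, annotator-specific systematic shapes (noise is
isotropic in angle), and spatially correlated bernoulli errors. Passing the
synthetic benchmark therefore demonstrates correctness of the fusion
machinery under the stated noise models, not performance on any particular
real imaging modality.

The standard study conditions used throughout the tests are: disk of
radius 20 on a 64 × 64 canvas with 5 boundary raters of amplitude 2 px
(consensus-gain and bracketing properties, 20–50 seeds); disk of radius 30
on 128 × 128 with 5 bernoulli raters, `p = 0.90`, `q = 0.98` (STAPLE
recovery, 10 seeds); and a 10-case benchmark with 6 raters per case
mirroring the structure of a multi-annotator comparison. These sizes keep
the full suite within a few tens of seconds on one CPU while leaving each
property statistically meaningful.

## Numerical choices and degenerate inputs

* Strict `> 0` binarization after luminance collapse accepts both 0/1 and
  0/255 masks with no threshold knob; multi-object masks are an error, not
  a warning, because the tool fuses exactly one object per mask.
* Multi-page TIFFs (3D stacks) are rejected; sections must be supplied as
  independent 2D masks.
* `order_polar()` fails on point sets coincident with the centre;
  interpolation closers require at least 3 distinct angular samples;
  active-contour closers reject collinear point sets (no enclosed region).
* A region touching the image border has no external perimeter
  (border-clip error) — shapes must keep a margin.
* Thinning idempotence is the package's operational definition of
  "one-pixel wide"; every fusion output is a fixed point of `thin_mask()`.
* STAPLE's degenerate cases: an all-foreground or all-background majority
  vote aborts (degenerate-vote error); non-convergence at `max_iter` warns
  but returns the current consensus.

## Limitations

* The polar closing model approximates non-star-shaped contours.
* The equidistant band midline and the pixel-group consensus are faithful
  to their verbal specifications but are one of several defensible
  discretizations; both are exercised against independent geometric oracles
  in the test suite.
* The Jaccard benchmark scores filled regions; boundary-distance metrics
  (e.g. Hausdorff) are deliberately out of scope.
* No multi-label fusion, no soft probability maps beyond STAPLE's internal
  posterior, no 3D fusion.
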