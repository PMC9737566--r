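---
title: "Methods: seed silhouette morphometrics with seedshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed silhouette morphometrics with seedshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshape)
```

This vignette is the package's own account of its methods: the measurement
model, the reconstruction choices made where the published workflow is
under-specified, the synthetic world used for testing, and the numerical
decisions that affect results. It states no empirical claim that the test
suite does not itself compute.

## 1. The measurement model

A silhouette is a simple closed polygon in millimetres, counterclockwise,
with an implicit closing segment. All descriptors are computed
analytically on the polygon, not on pixels:

* area by the shoelace formula, perimeter as the vertex-chain length;
* **L and W are the major/minor axes of the moment-equivalent ellipse**:
  the ellipse with the same normalized second central moments as the
  polygon interior, computed by exact Green-theorem moment integrals.
  This is the convention of the common image-measurement tools (and of
  scikit-image's region properties), *not* Feret calipers; it makes
  roundness R = 4A/(πL²) exactly b/a for ellipses. Feret-based axes would
  be systematically larger on ornamented outlines.
* solidity uses the convex hull of the polygon vertices
  (`grDevices::chull`).

Degenerate inputs — fewer than 3 distinct vertices, |area| < 1e-9 mm²,
self-intersection — are hard construction errors and are never silently
repaired: a self-intersecting "silhouette" is evidence of a failed
extraction, and repairing it would bias P and C invisibly.

### Raster to contour

Mask extraction thresholds a grayscale image (Otsu by default; for
near-binary silhouette scans the between-class variance has a plateau of
equally good cuts and we take the plateau midpoint), auto-detects
polarity from the border mean, keeps the largest 8-connected component,
always fills holes (solidity semantics require solid figures), and traces
the 0.5-level boundary by marching squares (`isoband`). The
marching-squares polygon is a 90°/45° staircase whose length
overestimates a smooth boundary by ≈ 5.5% *independently of resolution*;
we therefore apply three corner-cutting smoothing passes along the ring,
which bring the perimeter bias to ≈ +0.4% while moving vertices by well
under a pixel. Perimeter measured on pixel-edge chains was rejected for
exactly this inflation reason. Residual consequences:

* rasterized circularity carries a ≈ −1% bias (P enters squared);
* rasterized solidity of convex figures lands in [0.995, 1.0] at 512 px —
  hence the reporting convention that S ≥ 0.995 counts as "convex within
  tolerance". Exact S = 1 is unattainable on rasters.

Calibration is deliberately manual: two ruler points and a known
distance. Automatic ruler detection is out of scope; a supervised
calibration matches how scale bars are actually used in seed photography.

## 2. Average silhouettes

The published workflow builds per-species average silhouettes from ~20
seeds but does not specify the algorithm in reproducible detail. The
package's reconstruction is deliberately explicit and parameterized:

1. each mask's contour is aligned: centroid to origin, principal axis
   horizontal, 180° ambiguity resolved by the third moment along the
   axis (heavier half to +x);
2. for lateral views, an additional flip puts the hilum notch on the −x
   side. The notch is located as the minimum of the **low-pass radial
   profile** (harmonics 0–3 only). Using the raw deepest point fails on
   papillose seeds, where an ornament slot can be locally deeper than
   the notch, flipping seeds inconsistently and visibly corrupting the
   consensus — this was observed, not hypothesized;
3. rotation is applied to the *contour*, which is then re-rasterized
   (nearest-neighbour, binary-preserving); rotating rasters would
   introduce grey interpolation artifacts;
4. optionally (default on) each seed is rescaled to a common reference
   area, so every seed votes equally regardless of size — whether the
   original method scale-normalizes is unknown, so the flag is exposed
   and recorded in the output sidecar;
5. the aligned masks are stacked by integer accumulation (bit-exact
   under permutation of inputs) and thresholded at inclusion fraction
   ≥ 0.5; ties at the threshold are foreground.

The consensus boundary is the marching-squares contour of the largest
component of the thresholded stack. Averaging perturbed variants of a
base shape provably smooths: the consensus loses high-frequency ornament,
so its circularity exceeds the mean individual circularity — most
strongly for the most ornamented groups. Both effects are asserted by the
test suite on the synthetic study.

## 3. Seed models and the J index

Lateral views are cardioid-related: the base curve is
r(θ) = 1 − e·cosθ with eccentricity e ∈ [0, 1] and a raised-cosine hilum
notch of depth h and angular width w_h carved at θ = 0. Dorsal views are
ellipses (axis ratio ≥ 1) with optional symmetric raised-cosine
concavities at θ = ±π/2 — the "channeled back" morphology. Clean figures
(h = 0, d = 0, e ≤ 0.5) are convex; the cardioid base itself develops a
concavity near the hilum for e > 0.5, which is botanically meaningful
(strongly open hilum region) and so is not forbidden.

The **J index** between two outlines is 100 × intersection/union after
normalizing both to centroid–principal-axis–unit-area pose, evaluated by
rasterizing both polygons on a shared fine grid (512 px default); the
residual 180° ambiguity is resolved by taking the flip of the second
shape that maximizes overlap. Two points matter:

* IoU was chosen because it is symmetric and bounded in [0, 100].
  Earlier literature variously uses shared-area-over-total-area; absolute
  J values from this package are therefore **not comparable** with
  J tables published elsewhere, only orderings are.
* alignment is principal-axis only, no exhaustive rotation search: both
  seed views have a well-defined major axis, and the two-candidate flip
  handles the only real ambiguity. A full rotation search would be
  slower and could overfit ornament phase.

The historical discrete model catalogues (a handful of fixed lateral and
dorsal figures) are replaced by this continuous family;
`fit_seed_model()` (cyclic coordinate search, shrinking steps, 3
restarts) answers "which figure adjusts best" within it.

## 4. The synthetic world

The generator exists so that every downstream stage is testable without
the original photographs. Its defaults are a *stated world*, chosen once:

| parameter | default | rationale |
|---|---|---|
| seeds per species | 20 | the sample size used per species in outline studies |
| within-species area CV | 10% | plausible for seeds of one plant; not printed in the source data |
| across-species area CV | 45% | reproduces the observed pattern that area/perimeter dominate the overall CV (≈ 55% across species) |
| group mean lateral areas | 1.31/1.19/0.89/1.22 mm² | the published group means (smooth/rugose/echinate/papillose) |
| ornament amplitude a | 0 / 0.04 / 0.06 / 0.22 | group definitions: none / rounded tubercles / acute spines / long papillae; mid-range of the stated bands |
| ornament shape | — | raised-cosine bumps (rugose), narrow triangles (echinate), broad flat-topped trapezoids with narrow slots (papillose) |
| ornament count | 9 / 14 / 8, jittered ±1 per seed | matches the visual grain of each group; the ±1 jitter decorrelates ornament positions across seeds, without which aligned slots can survive into the consensus |
| lateral elongation | 1.17 ± 7% per seed | brings lateral AR near 1.25; the jitter gives AR and roundness their natural dispersion |
| hilum notch | depth ±20%, width ±15% per seed | seeds vary in how open the hilum region is; gives solidity realistic within-species spread |
| shape wobble | harmonics 2–4, ≤ 1.5% of radius | no two real seeds are the same model figure; this is the variation averaging is meant to remove |

All randomness flows from one integer seed per species, so every table in
the test suite is reproducible bit-for-bit.

What the generator does **not** emulate: testa cell mosaics and surface
texture (only the outline), photographic artifacts (shadows, glare,
focus), multi-seed scenes, and the long taxonomic tail of real shape
diversity. A green test therefore establishes that the *pipeline*
recovers the structure a four-group world produces — not that the
specific published means are reproduced. Published absolute values also
inherit an unknown from the source: whether perimeters were measured on
raw or smoothed boundaries is not stated there, so only qualitative
orderings (which group is lowest, which descriptor varies least) are
asserted anywhere in this package.

## 5. Group statistics

CV = SD/mean × 100 with the sample (n−1) SD. Kruskal–Wallis uses
midranks with the standard tie-correction 1 − Σ(t³−t)/(N³−N); if every
observation is tied the statistic is defined as H = 0, p = 1. P-values
come from the χ² approximation; an exact complete-enumeration p is
available for total n ≤ 12 and backs the oracle tests.

The step-down procedure orders groups by mean rank and applies closed
testing over contiguous subsets: the full set at level α; on rejection,
the two maximal contiguous subsets of size k−1; and so on, each subset
**re-ranked internally** before its test — re-ranking is the defining
feature of the procedure, not an implementation detail. A subset of size
p < k is tested at α_p = 1 − (1−α)^((p−1)/(k−1)). The cited literature
does not fix one α-adjustment formula; this one is the common choice, and
`adjust = "none"` switches to plain α at every step for sensitivity
analysis. Subsets contained in an accepted subset are never tested
(closure), accepted subsets are the homogeneous subsets, and letters are
assigned left-to-right in mean-rank order — two groups share a letter iff
they co-occur in a subset. Monte-Carlo familywise error at k = 4,
n = 20/group sits at ≈ 0.044 for α = 0.05 (asserted in the tests with
band [0.035, 0.065]).

One behavioral reproduction: descriptors whose omnibus test accepts are
flagged `excluded` in group tables (no letters reported). In the
published analysis aspect ratio and roundness of lateral views were
dropped this way; here it is behavior, not a hard-coded exclusion list.

## 6. Numerical choices and degenerate cases

* Simplicity checking is exact (segment-pair intersection with
  bounding-box prefilter); generated radial outlines skip it as they are
  simple by construction.
* Rasterization samples pixel centers with even-odd scanline fill;
  scanlines through a vertex (odd crossing counts) are skipped rather
  than patched — at most one pixel row per vertex coincidence, and only
  at exact floating-point equality.
* `j_index` on disjoint shapes is 0, not an error.
* Averaging requires ≥ 2 masks; the pipeline treats a single-seed
  species' "average" as its aligned individual.
* Letters use `letters[]`; more than 26 homogeneous subsets is not a
  realistic regime for k ≤ 26 groups.
* The canvas for alignment must contain the rotated, rescaled mask;
  too-small canvases are an error, not a crop.

## 7. Known limitations

* Solidity of rasterized convex shapes saturates at ≈ 0.998, not 1.0;
  comparisons of S close to 1 are resolution-limited below ~0.2%.
* The J index is not comparable in absolute value with
  shared-area-over-total-area similarity indices.
* The averaging procedure is a faithful-behavior reconstruction, not a
  reimplementation of the original (unpublished) algorithm; its
  scale-normalization default is a choice, recorded in every output.
* Group labels are always user-supplied (or generator ground truth):
  the package never classifies a real seed into an ornamentation group —
  in the source workflow that judgment is made by an expert, and
  automating it is explicitly out of scope.
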