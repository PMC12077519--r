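---
title: "Cortical bone cartography of phalangeal diaphyses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone cartography of phalangeal diaphyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phalmap)
```

## The analytical problem

Hand use leaves a mechanical signature in the cortical bone of the finger
bones. Great apes, which load their phalanges in flexed-finger locomotion,
concentrate cortex along the palmar flexor-sheath ridges and show mean
cortical thickness rising steadily from the base toward the trochlea;
humans, whose phalanges are loaded mainly in manipulation, thicken the
dorsal shaft and show a mid-to-distal thickness peak followed by a distal
decline. `phalmap` turns a pair of triangle meshes — the outer (periosteal)
and inner (endosteal) surfaces of a phalangeal diaphysis segmented from
micro-CT — into quantitative descriptors of that signature:

1. an unrolled **cortical thickness map** (97 shaft levels x 50
   circumferential rays),
2. **cross-sectional mechanical properties**, chiefly the polar second
   moment of area *J* (a proxy for bending/torsional rigidity),
3. **longitudinal curvature** via the included angle, and
4. **multivariate group comparison** of maps by PCA, canonical variates
   analysis (CVA), one-sample Hotelling T² tests and typicality
   probabilities.

Because no public corpus of fossil/museum phalangeal surface pairs exists
at the resolution this protocol expects, the package carries a first-class
**synthetic phalanx generator** with a known ground-truth thickness field.
All validation is parameter recovery against that ground truth.

## Coordinate conventions

Every analysis runs in a canonical anatomical frame: `u` proximal to
distal, `v` dorsal, `w = u x v` radial for a right-hand bone, origin at
the proximal extreme. `orient_anatomical()` recovers this frame
automatically from the vertex scatter:

* `u` is the dominant principal axis, signed so the broader end (the
  base; compared by mean outer section area over the two end deciles) is
  proximal.
* `v` is the cross-section axis that carries the palmar bow of the
  section centroids, signed so the bow points to −v (phalanges bow
  palmarly). We deliberately do **not** take "the second principal axis":
  phalangeal sections are wider radioulnarly than dorsopalmarly, so the
  dorsopalmar direction is usually the *third* axis of the scatter. For
  straight bones (no detectable bow) the flatter (smaller-spread) section
  axis is used with a deterministic sign rule.
* Bones with near-isotropic scatter (elongation ratio < 1.2, e.g. a
  sphere) are rejected rather than guessed at. Both `u` and `v` can be
  overridden with explicit `hints`.

Left-side bones are reflected across the u–v plane (`mirror_to_right()`)
so that all maps share one angular convention; mirroring twice is the
identity, and an unmirrored left map is exactly the angular reversal of
its mirrored counterpart about the mid-dorsal column.

The orientation recovered here is a reproducible, deterministic surrogate
for the operator-placed "standard anatomical position" of interactive
workflows; it is not an attempt to reproduce any operator's choices.

## The mapping protocol

The shaft is defined as a window of maximum bone length, default
(0.20, 0.80) — wide enough to clear both epiphyses on all the synthetic
shapes while retaining most of the diaphysis. The window is configurable
and recorded in every output, because published shaft definitions vary.
Within the shaft, 97 cross sections are taken at 1% intervals of shaft
length from 2% to 98%. On each section, 50 rays leave the area centroid
of the outer contour at equal 7.2° steps, starting mid-dorsal and turning
counterclockwise viewed from distal. The landmark on each surface is the
**farthest** ray–contour intersection (this guarantees outer ⊇ inner
ordering on non-convex contours), and cortical thickness is the distance
between the paired landmarks. Three deliberate conventions:

* Rays originate at the **outer-contour area centroid**, not the
  cortical-area centroid — the simplest reading of a centroid-ray
  protocol, and the one that makes solid sections well defined.
* If the section has no inner contour (solid bone, e.g. near a capped
  medullary cavity) or a ray misses it, the inner landmark falls back to
  the centroid, the cell records the full centroid-to-surface radius, and
  a parallel Boolean mask flags the cell. Flagged cells are excluded from
  means and imputed (group column mean) before PCA; counts are logged,
  never silently absorbed.
* Sections are planar and perpendicular to `u`, matching standard
  cross-sectional practice; we do not slice perpendicular to the curved
  centerline.

Maps are standardized by dividing every cell by the bone's maximum length
(`standardize_map()`), making them dimensionless and size-comparable;
re-standardizing is a contract error, and mixing standardization states
in means or sample matrices is rejected.

## Mechanics and curvature

`polygon_moments()` evaluates area, centroid and second moments of the
section contours with closed-form Green's-theorem sums — exact for
polygons, no quadrature. `section_J()` subtracts inner from outer
moments, moves them to the cortical centroid by the parallel-axis
theorem, and reports `J = Ixx + Iyy`. The independent check in the test
suite is a scanline pixel-rasterization oracle (4000² grid), plus the
analytic annulus (`J = (π/2)(r_o⁴ − r_i⁴)`) and square tube
(`J = (s_o⁴ − s_i⁴)/6`). One physical note: moving the medullary cavity
off-center *lowers* the centroidal J relative to the concentric case with
equal areas, because off-center removal takes away material of higher
r²; both routes (closed form and rasterization) agree on this.

J is evaluated at 35, 50 and 65% **of maximum bone length** — a different
reference frame from the map grid, which uses shaft-length fractions;
both frames are kept explicit in output metadata. Standardization uses
`J / L⁴` by default: the exponent 4 is the dimensionally homogeneous
choice, but it is a first-class argument (`standardize_J(..., exponent=)`)
and is echoed in every output row, since published practice sometimes
standardizes by other powers of length.

Curvature is the **included angle**: section centroids over the shaft
window are projected to the sagittal plane and a circle is fitted (Kåsa
algebraic fit, then one Gauss–Newton refinement). Because the centroids
cover only the shaft window, the fitted arc is extended to the full
proximodistal extent of the bone before the subtended angle is taken —
this reports whole-bone curvature rather than the window's fraction of
it, and recovers a generator angle of 45° to within a few hundredths of
a degree on noiseless meshes. Bones whose fitted radius exceeds 50x the
shaft length are reported as straight (0°); the threshold is arbitrary
but documented and configurable.

## Group statistics

Standardized maps are flattened row-major (level-major) into an
n x 4850 matrix. PCA is column-mean centered and **unscaled** — cells
share one unit, so variance scaling would only amplify noise cells; a
scaled variant exists behind a flag for completeness. Axis signs follow a
deterministic convention (largest-|loading| entry positive) so scores
reproduce across platforms. CVA runs on the first three PC scores
(configurable), whitening the pooled within-group covariance via Cholesky
so canonical distances are Mahalanobis distances. Typicality
probabilities are upper chi-square tails of the squared canonical
distance to a group centroid, with an F-based small-sample variant
selectable and labeled in output — both conventions circulate in the
morphometric literature and the choice is never silent. One-sample
Hotelling T² follows the classical `F = T²(m−p)/(p(m−1))` transform.

Leave-one-out validation refits the CVA without each specimen and
assigns by nearest canonical centroid. On reference cohorts whose
morphotype amplitudes exceed within-group variation several-fold this
reaches accuracy 1.0, and a 50/50 parameter blend projects between the
two group centroids on CV1 — the synthetic analog of an intermediate
fossil.

## The synthetic phalanx generator

`generate_phalanx()` sweeps elliptical sections (dorsopalmar/radioulnar
aspect 0.8) along a circular-arc centerline bowing palmarly, with a
quadratic radius profile through base (6 mm), midshaft (4.5 mm) and
trochlea (5 mm) that flares the metaphyses enough to exercise shaft
cropping — no articular morphology is modeled. The inner surface offsets
the outer one inward along in-plane rays from the section center by the
ground-truth field

t(s, θ) = t₀ + A_ax·ax(s) + A_d·dors(θ) + A_r·win(s)·ridges(θ),

with `ax` either a smooth monotone rise ("ape-like") or a Gaussian bump
at `peak_frac` ("human-like"), `dors` a raised cosine over mid-dorsal
± 60°, and two Gaussian ridges flanking the palmar midline (± 1 rad,
angular sd 0.35) inside a smooth axial window (0.25–0.95). Every
generated bone returns the field as a callable plus its exact sample on
the 97 x 50 analysis grid, so recovery error is measurable cell by cell:
noiseless recovery is ≤ 0.2% of local thickness at mesh resolution
(400, 200), against a 3% acceptance envelope (thickness is measured along
*centroid* rays while the generator offsets along *section-center* rays,
so exact equality is not expected).

Reference cohorts (`reference_group_specs()`) fix the study conditions:
ape-like (ridge amplitude 1.5 mm, monotone profile, 40° curvature,
L = 42 mm) versus human-like (dorsal amplitude 1.0 mm, mid-peak at 0.65,
20° curvature, L = 40 mm), 15 individuals per group. Between-individual
variation is multiplicative log-normal on amplitude-like parameters
(10% relative sd on thickness amplitudes, 5% on length) and additive
normal on positional ones (0.05 on `peak_frac`, 3° on curvature) — the
multiplicative/additive split keeps positivity invariants intact under
perturbation, and invalid draws are resampled (at most 100 tries).
Surface noise is i.i.d. radial vertex jitter (0.02 mm), a roughness
model; it does **not** emulate segmentation bias, partial-volume effects,
trabecular remnants or damaged articular surfaces, so passing tests here
demonstrate protocol correctness, not robustness to real segmentation
pathology.

## Numerical choices and degenerate inputs

* Plane–mesh intersections chain triangle crossings by shared mesh
  edges; vertices exactly on a slicing plane are nudged by an
  infinitesimal epsilon. Multiple loops keep the largest by area (count
  logged); open chains (boundary-touching slices) are dropped.
* Ray–polygon intersection tolerates endpoint grazing by counting a
  shared-vertex hit on both adjacent edges — duplicates are harmless
  because only the farthest hit is used, while a lost hit would be fatal.
* Profile peaks are located after a centered moving-average smoothing
  (window 5 rows ≈ 5% of shaft) to suppress argmax jitter on noisy
  meshes; ties break to the proximal-most level; the window is an
  argument and the raw profile is what gets exported.
* The typicality calibration experiment uses four reference groups of
  2000 draws: the chi-square transform assumes a known within-group
  covariance, and this group size makes estimation distortion negligible
  next to the Kolmogorov–Smirnov test's own resolution at n = 2000.
* Problem sizes in the routine test/validation runs: cohorts of 2 x 15
  bones at mesh resolution (200, 100), recovery checks at (400, 200),
  2000 replicates for the Hotelling size and typicality uniformity
  checks. These sizes were chosen so each property is measured with
  comfortable margin over its tolerance.

## Known limitations

* Binary PLY input is not supported (ASCII PLY/OBJ/STL and binary STL
  are); convert binary PLY before loading.
* Sections are planar along `u`; strongly curved bones therefore sample
  slightly oblique anatomical sections near the ends, as in standard
  practice.
* Automatic orientation needs either a palmar bow or a dorsopalmar
  flattening to resolve `v`; perfectly circular straight tubes resolve
  by a documented but arbitrary sign rule — pass `hints` for such cases.
* The generator's epiphyses are radius flarings, not articular surfaces;
  digit attribution, behavioral inference and segmentation are out of
  scope.
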