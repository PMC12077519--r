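# phalmap — cortical bone cartography of phalangeal diaphyses

`phalmap` quantifies how cortical bone is distributed in finger bones
(phalanges), for comparative and paleoanthropological work on manual
behavior. Starting from paired triangle meshes of the outer (periosteal)
and inner (endosteal) shaft surfaces — the usual product of micro-CT
segmentation — it computes:

* **Unrolled cortical thickness maps.** The diaphysis (default window
  20–80% of maximum bone length) is cut into 97 cross sections at 1%
  intervals of shaft length (2–98%). On each section, 50 equiangular rays
  leave the outer-contour centroid; cortical thickness is the distance
  between the paired outer/inner semi-landmarks on each ray, giving a
  97 × 50 level-by-angle matrix, standardized by maximum bone length.
* **Cross-sectional mechanics.** Closed-form (Green's theorem) polygon
  moments of the cortical annulus; the polar second moment of area
  *J* = Ixx + Iyy at 35/50/65% of bone length, standardized as *J*/L⁴.
* **Longitudinal curvature** as the included angle of a circle fitted to
  the sagittal-plane section centroids.
* **Group statistics.** PCA of the map matrices (centered, unscaled),
  CVA on the first three PC scores with Mahalanobis-whitened canonical
  space, leave-one-out classification, one-sample Hotelling T² tests,
  and chi-square (or small-sample F) typicality probabilities.
* **A synthetic phalanx generator** — parametric tubular bones with
  longitudinal curvature, flexor-sheath-ridge vs dorsal thickening,
  monotone ("ape-like") vs mid-peaked ("human-like") proximodistal
  thickness profiles, and group-structured cohorts with a known
  ground-truth thickness field for validation.

See `vignettes/cortical-cartography.Rmd` for the model, conventions and
design decisions.

## Worked example

```r
library(phalmap)

# a synthetic bone with known ground truth: palmar ridges + dorsal band
gen <- generate_phalanx(phalanx_spec(
  included_angle_deg = 30,
  thickness_field = thickness_field_spec(
    t0 = 1.2, axial_profile = "monotone_increase", axial_amp = 0.8,
    dorsal_amp = 1.0, ridge_amp = 1.5),
  mesh_resolution = c(400, 200)))

m <- compute_thickness_map(gen$pair)   # 97 x 50 mm-valued map
max(abs(m$values - gen$truth$values) / gen$truth$values)
#> [1] 0.001566669        # worst-cell recovery error, 0.16%

included_angle(gen$pair)$included_angle
#> [1] 45.00021           # for a spec with included_angle_deg = 45

# mechanics against the analytic annulus (r_o = 5, r_i = 3)
th <- seq(0, 2 * pi, length.out = 4097)[-4097]
section_J(cbind(5 * cos(th), 5 * sin(th)),
          cbind(3 * cos(th), 3 * sin(th)))$J
#> [1] 854.5125           # (pi/2)(5^4 - 3^4) = 854.5132
```

The numbers above are what the acceptance run prints: the mapping
pipeline recovers a structured thickness field to well under 1% per
cell, curvature to a few 1e-4 degrees, and *J* to < 0.01% of the closed
form.

A full simulated study lives in `analysis/` (run in order):

```sh
Rscript analysis/01_simulate_cohorts.R    # 2 x 15 bones + 1 blended "fossil"
Rscript analysis/02_cartography.R         # maps, mean models, profiles
Rscript analysis/03_mechanics.R           # J at 35/50/65%, included angle
Rscript analysis/04_group_statistics.R    # PCA/CVA/LOO/typicality/T2
```

The final script reports, for the intermediate (50/50 parameter blend)
specimen projected into the reference CVA:

```
leave-one-out CVA accuracy (reference groups): 1
blend specimen:
  CV1 = 0.243  (group centroids: 8.009 / -8.009)
  Hotelling T2 vs ape_like:   T2 = 789.8,  F(3, 12) = 225.7,  p = 8.13e-11
  Hotelling T2 vs human_like: T2 = 3619.7, F(3, 12) = 1034.2, p = 9.58e-15
```

i.e. the two morphotypes separate perfectly, and the blend falls between
the group centroids on CV1 while differing significantly from both —
the synthetic analog of an intermediate fossil placement.

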