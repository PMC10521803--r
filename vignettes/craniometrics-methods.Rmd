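---
title: "Methods: photocephalometric measurement and cranial mean-shape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photocephalometric measurement and cranial mean-shape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniometrics)
```

## The measurement model

Children operated for sagittal synostosis are followed with 3D surface
photogrammetry because it is fast and radiation-free. The quantities of
clinical interest — head length and width, circumference, cephalic index and
intracranial volume — are all defined relative to an anatomical frame, so
the pipeline is: register, slice, measure, standardise.

**Registration.** Three landmarks (nasion, left and right tragus) define the
reference plane. The registration is a closed-form rigid map: the landmark
centroid goes to the origin; the in-plane left→right tragus direction
becomes +x; the plane normal (signed so the cranial vertex is above) becomes
+z; the nasion therefore lands on the +y half-axis. A second, in-plane
translation then re-anchors the origin at the centroid of the axial slice
with the largest perimeter (the head circumference slice). Two choices here
were genuinely open:

- The three x/y/z rotations are realised as a single equivalent rotation
  matrix rather than iteratively fitted Euler angles — same map, no
  convergence concerns.
- The re-anchoring translation deliberately leaves z untouched, so the
  nasion–tragi plane stays exactly at z = 0. Whether the anchor should also
  move z is unspecified in the clinical definition; keeping the plane fixed
  preserves the meaning of "height above the reference plane".

Axis polarity (left→right = +x, anterior = +y, superior = +z) is a package
convention; it makes "anteroposterior" unambiguous for the OFD and is
resolved by the landmark *labels*, so a mirrored or arbitrarily posed scan
still registers with a proper (det +1) rotation.

**Slicing.** Axial planes are stepped from the reference plane to the vertex
(default step 1 mm; bounds are a package choice — the clinically relevant
vault lies above the plane). Each mesh–plane section is computed exactly per
triangle and chained into closed loops through shared mesh edges; the
largest-perimeter loop is kept, which discards small spurious loops when a
plane clips an ear or the nose. The slice maximising the OFD is selected,
ties broken toward the inferior slice; sagittal and coronal sections pass
orthogonally through its centroid. Requiring loops to close makes
non-watertight regions fail loudly rather than silently undermeasure.

**Measurements.** OFD and BPD are axis-aligned extents (max − min along +y
and +x) of the maximal axial contour: after registration these axes *are*
the anatomical anteroposterior/transverse directions, matching the clinical
caliper definition of head length and width. A rotating-calipers maximum
chord is available (`method = "calipers"`) for sensitivity analysis but is
not the default. OFC is the closed-contour perimeter. Cephalic index is
100·BPD/OFD.

**Intracranial volume.** The volume above the reference plane is computed by
the divergence theorem with the field F = (0, 0, z): crossing triangles are
clipped to z ≥ 0 and the planar cut contributes zero flux, so no cap
triangulation is needed; global orientation is fixed by the full-mesh signed
volume. Photogrammetric volumes overestimate ICV (scalp, cap), so the
result passes through a linear correction `slope·raw + intercept` fitted by
OLS on paired same-day CT volumes. **No literature correction constant is
shipped**: until calibrated, the identity correction is used, because
shipping an invented constant as truth would be worse than reporting the raw
overestimate.

**z-scores.** Each measurement is standardised against an age/sex
growth-reference table, linearly interpolated in age; out-of-range ages
clamp to the nearest row with a warning (references are silent on
extrapolation, and clamping is the conservative choice for a 6-year
follow-up range). The tables shipped by the generator are synthetic
stand-ins; real published tables are supplied as CSV
(`measurement,sex,age_months,mean,sd`).

## 120-point correspondence and mean shapes

Group mean shapes need pointwise correspondence across subjects. Every
closed slice is resampled at 120 equally spaced *angles* about its area
centroid, starting at the local ordinate (anterior for axial slices,
superior for sagittal and coronal) and proceeding counterclockwise, so
sample k always means angle 3k degrees in the same anatomical frame. Angular
(rather than arc-length) parameterisation was chosen because arc-length
correspondence drifts when one subject has a local bump (an occipital
bullet would shift every downstream point), while angles about the centroid
stay anatomically stable for the star-shaped contours of the cranial vault.
Contours that are not star-shaped about their centroid are rejected with the
offending angle rather than silently mis-sampled.

One note on frames: a coronal section lies in a plane y = const, so its
in-plane ordinate is +z (superior); the anterior axis is not available
there. Axial slices start at +y (anterior), sagittal and coronal at +z.

The group model stores the coordinate-wise mean of each sample and the SD of
the subjects' radial distances at that index (n−1 denominator; 0 for a
single subject). A scalar radial SD — not a 2D covariance — is what a
clinician reads off a mean-shape band plot, and it is well defined under the
angular correspondence. Deviation profiles against a reference shape report
the signed radial difference and, where the reference SD is positive, its
standardised version.

## The synthetic world

Patient scans are not distributable, so the generator produces closed
surfaces with known ground truth: an ellipsoid (full height above the
reference plane, a shallow 0.35·height cap below, so the landmarks sit on a
genuine closed head-like surface) deformed by *radial* Gaussian bumps —
frontal bossing at the anterior-superior pole, an occipital bullet just
above the posterior reference plane, and vertex flattening as a radial
indentation of depth `vertex_flattening·height` at the vertex. Flattening
was deliberately implemented radially rather than as a z-compression: every
deformation being radial keeps the surface star-shaped, so the reference-
plane contour is available in closed form (directions with dz = 0 lie
exactly in the plane) and the volume reduces to a 2D quadrature of r³ —
cheap, independent ground truth for every stage.

Default anatomy (chosen once, as plausible paediatric values): normocephalic
cephalic index 80 ± 3, scaphocephalic 68 ± 3 with 2 mm bossing and a 3 mm
bullet; head length grows as `190 − 72·exp(−age/14)` mm (118 mm at birth,
saturating near 190 mm), height 0.62 of length, a joint size factor with 3%
CV coupling length/width/height (which is what makes OFC a strong ICV proxy
in synthetic cohorts, as it is in real ones), vertex noise 0.2 mm, and
icosphere subdivision 4 (5120 faces — contour and volume discretisation
errors of order 0.05% and 0.2%, far below the acceptance tolerances).

Synthetic reference tables are Monte-Carlo summaries of the same (bump-free)
growth model using closed forms (Ramanujan ellipse perimeter, half-ellipsoid
volume). A planted cohort offset (`ofc_offset_sd`) is expressed in
*reference-table SD units*: the table's OFC SD includes cephalic-index
variation on top of the size CV, so the generator first estimates
sd(OFC)/mean(OFC) under the model and scales the size shift accordingly —
without this the "+1 SD" cohort would actually sit at +0.9 SD.

What a green test does **not** establish: the generator has no face, ears,
hair/cap artifacts, scanner holes or landmark placement error beyond a small
surface offset; real-data performance therefore rests on the geometric
invariances (rigid invariance, idempotence, closed-form recovery), not on
cohort realism.

## Statistical procedure

Group comparisons operate on z-scores, not raw values, removing age/sex
structure before testing. The gate tests normality per group (Shapiro–Wilk)
and homogeneity of variance (Levene on absolute deviations from group
means), both at the same α = 0.05 as the comparison itself (the gate
threshold is not separately specified anywhere authoritative; reusing α is
documented rather than hidden). All gates passing selects classical one-way
ANOVA with pooled-SD pairwise t tests post hoc; otherwise Kruskal–Wallis
with the Conover–Iman rank test,

t = (R̄ᵢ − R̄ⱼ) / sqrt( S²·(N−1−H)/(N−k)·(1/nᵢ + 1/nⱼ) ),

with midranks for ties and Student-t reference on N−k degrees of freedom.
Bonferroni correction is applied to *both* post hoc families — whether the
parametric branch was also corrected is ambiguous in common practice, and
correcting both is the conservative, consistent choice. Degenerate inputs
are handled explicitly: constant groups fail the normality gate (Shapiro is
undefined there), all-tied data yields an omnibus p of 1, and groups with
n < 3 are refused.

The full gated procedure is calibrated by simulation: over 1000 null
replicates (3 × n = 30 standard normals) the omnibus rejection rate must
stay within [3.5%, 6.5%] at α = 0.05 — the gate re-routes ~15% of null
samples to Kruskal–Wallis, and the acceptance suite checks the combined
procedure, not each branch in isolation.

## Numerical choices

- Duplicate-vertex merge at 1e-6 mm (STL stores vertices per facet; merging
  is required before watertightness can even be assessed).
- Plane–vertex degeneracies: if a section plane passes within 1e-9 mm of a
  vertex it is nudged 1e-7 mm along its normal — well inside the 1e-6 mm
  contour planarity tolerance, and deterministic, so registered re-runs
  reproduce bit-for-bit.
- Ray–polygon sampling tolerates s ∈ [−1e-9, 1+1e-9] along segments and
  collapses double hits closer than 1e-6 mm (a sample ray passing exactly
  through a polygon vertex is otherwise counted twice or zero times).
- Unit heuristic: a head scan's maximum extent should lie in 120–400 mm;
  anything else warns about metres/centimetres instead of silently
  rescaling.
- Slice-search ties break toward the inferior slice; search step defaults to
  1 mm and the acceptance suite checks agreement with a 10×-finer search to
  within one step.

## Known limitations

- Axis-extent OFD/BPD and angular resampling are *documented package
  choices*; other implementations may use caliper diameters or arc-length
  sampling and will differ at the sub-millimetre level.
- ICV uses the nasion–tragi plane as the inferior cut; true intracranial
  volume has no sharp photogrammetric boundary, which is exactly why the CT
  calibration exists.
- The registration anchor (centre of mass of the largest-circumference
  slice) averages out anisotropic growth effects; it is a stable reference,
  not a tool for localising where growth happened.
- Non-watertight meshes are accepted for contour measurements but refused
  for volume estimation.
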