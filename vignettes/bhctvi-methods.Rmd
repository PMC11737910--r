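---
title: "Breath-hold CT ventilation imaging: models, phantom and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold CT ventilation imaging: models, phantom and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bhctvi)
```

## The measurement model

Breath-hold CT ventilation imaging derives a surrogate map of regional lung
function from a pair of CT scans, one at expiration and one at inspiration.
Deformable image registration (DIR) aligns the inspiration scan to the
expiration scan, assigning each expiration voxel a displacement vector
u(x, y, z) in millimetres that points at the corresponding inspiration-phase
position. The local volume-change factor is the Jacobian determinant of the
deformation,

V(x, y, z) = det(I + ∇u),

where ∇u collects the nine partial derivatives ∂u_i/∂x_j. V > 1 marks local
tissue expansion during inhalation, V < 1 contraction, V = 1 no change;
regions that expand most ventilate most. Within the two lungs the Jacobian
values are converted to percentile ranks (mid-rank ties), and voxels at or
above the 75th percentile are classified as *highly functional* — by
construction the top quartile of the in-lung ventilation distribution.

Reports then follow the lungs' cranio-caudal organisation: four axial
sections (apical, middle, basal, diaphragm) are intersected with each lung,
and the percentage of highly functional voxels in each section-lung cell is
tabulated. Because gravity redistributes ventilation toward the dependent
side, these tables change when a subject is scanned supine, prone, or in
lateral decubitus, and paired Wilcoxon signed-rank tests (two-sided, exact
for the cohort sizes involved, Bonferroni-corrected over the three
position contrasts, displayed threshold 0.016) quantify the differences.

### Percentile reference population

Percentiles are computed over **all voxels of both lungs combined**, not per
section. With per-section reference populations every section would contain
25% highly functional voxels by construction and the section table would be
uninformative; a global reference lets the table express *where* the top
quartile of ventilation sits. The mid-rank convention makes a constant map
rank 50 everywhere, so a degenerate ventilation map flags no voxels.

## The synthetic thorax phantom

No volunteer scans are distributed with this package, so validation rests on
a digital thorax whose deformation is known analytically:

* **Geometry.** An elliptical soft-tissue body (+40 HU; semi-axes 80 × 70 mm)
  contains two ellipsoidal lungs (−780 HU; semi-axes 26 × 36 × 50 mm,
  centres ±30 mm off the midline) and a posterior spine cylinder (+700 HU),
  in ambient air (−1000 HU). The default grid is 96³ voxels at 2 mm —
  a desk-scale stand-in for clinical 512² × 2 mm acquisitions; the default
  lungs hold ~390 mL at exhale, roughly one-seventh clinical volume. Patient
  axes are fixed: x right→left, y anterior→posterior, z inferior→superior,
  so the gravity unit vector is +y supine, −y prone, −x right lateral, +x
  left lateral.
* **Parenchymal texture.** Lung interiors carry a smooth seeded Gaussian
  intensity texture (SD 100 HU, ~10 mm correlation length) emulating the
  vascular and parenchymal heterogeneity that gives intensity-based
  registration its local contrast; a uniform-HU lung would make interior
  correspondence unobservable.
* **Scanner point-spread.** One separable binomial smoothing pass (σ ≈ 0.7
  voxel) is applied to each rendered phase, mimicking the CT reconstruction
  kernel and the partial-volume effect. Without it, point-sampled sharp
  boundaries alias ("pixel locking") and systematically bias any
  sub-voxel registration.
* **Ground-truth deformation.** Inside a taper window that falls smoothly to
  zero at the body surface (the chest surface is static between breath
  holds), each axis carries an affine strain whose product integrates to the
  requested mean Jacobian over the lungs — 1.30 by default, matching a
  typical tidal inhale/exhale lung volume ratio. On top of this sit: a
  *gravity gradient* (default slope 0.15 across the lung half-extent) that
  makes the dependent side expand more; a *diaphragm gradient* (default
  0.10) that makes basal lung expand more than apical; a cranio-caudal
  anchor at the lung apex (the diaphragm descends, the apex stays); and a
  bulk anti-gravity drift (6 mm supine, 3 mm lateral, 0 prone).
* **Position-specific structure.** The per-axis share of the expansion
  depends on position: supine breathing is chest-wall dominated
  (x:y:z = 0.20:0.40:0.40 of log expansion), prone breathing is almost
  purely cranio-caudal (0.48:0.06:0.46) with no bulk drift, lateral
  positions are mixed (0.28:0.30:0.42). These shares, together with the
  anchors, reproduce the qualitative observations the pipeline is meant to
  detect: supine displacement vectors run dorsal→ventral against gravity,
  prone vectors run head→feet parallel to the ground, and the highly
  functional areas sit on the dependent side in every position. The
  gradient slopes and axis shares are free parameters of the phantom, not
  values calibrated to any particular cohort.
* **Density rescaling.** The inhale image is rendered through the exact
  inverse deformation (fixed-point inversion of the analytic field) and
  parenchymal HU are rescaled as −1000 + (HU + 1000)/J, so local expansion
  dilutes density exactly as mass conservation dictates. Soft tissue is
  incompressible and keeps its HU. Gaussian noise (SD 20 HU) is added
  independently to both phases.
* **Determinism.** A phantom is a pure function of its specification and
  seed; identical inputs give bit-identical volumes.

What the phantom does *not* emulate: airway trees, vessels as discrete
structures, cardiac motion, lobar fissures, scanner physics beyond a
Gaussian kernel and additive noise, and hysteresis between inhale and exhale
pathways. Passing tests on the phantom therefore demonstrate the internal
consistency of the pipeline and its behaviour under a known smooth
deformation — not clinical accuracy on real thoracic CT.

## Registration

The displacement field is parameterised on a cubic B-spline lattice (12 mm
knot spacing by default) shared by all resolution levels, so level-to-level
hand-over is an exact coefficient addition and the bending penalty always
applies to the total field.

1. **Initialisation by exhaustive block matching.** A wide search (±32 mm)
   over 7³-voxel blocks at half resolution captures the bulk displacement;
   the moving image is then warped by that estimate and a narrow (±8 mm)
   full-resolution pass measures the residual. Every node is an exhaustive
   integer search with per-axis parabolic sub-voxel refinement, so this
   stage cannot be trapped by local minima; a relative magnitude penalty
   and a match-acceptance rule (a displaced match must beat the zero-offset
   score by 30%) suppress the aperture problem in translation-invariant or
   smooth-ramp regions, and nodes far from the median of their neighbours
   are discarded. Node displacements are fitted to the lattice by local
   Gaussian averaging, which suppresses the near-random single-node errors.
2. **Metric refinement.** L-BFGS-B minimises a voxel-weighted similarity
   metric (mean SSD by default, 1 − NCC as an option for strongly
   density-rescaled pairs) plus a bending-energy penalty on the lattice
   coefficients. The moving image is sampled with a cubic Keys interpolant
   whose *analytic* spatial gradient feeds the chain rule, keeping value
   and gradient exactly consistent — a finite-difference gradient of a
   linear interpolant creates voxel-scale artefacts in the optimisation
   landscape. Voxels inside the parenchyma HU band (−950 to −350) carry
   full weight; others 0.1, so the very strong body and mediastinum edges
   do not dominate the cost. Two levels are used by default (half and full
   resolution, 1 and 0 smoothing passes, bending weights 0.02 and 0.01)
   with the fixed-image sample grid thinned by a factor 2 for speed.
3. **Determinism and safety.** There is no stochastic sampling anywhere, so
   identical inputs give identical fields; a fold check warns when the
   recovered Jacobian drops to ≤ 0.05.

### Measured accuracy and a known limitation

On the default 96³ supine phantom (noise SD 20 HU) the recovered field has a
mean endpoint error of ≈ 1.1 mm (≈ 0.5 voxel) inside the lungs, and the
Spearman correlation between estimated and ground-truth Jacobian maps is
≈ 0.6. Diagnostic experiments (initialising the optimiser at the ground
truth and converging to machine precision) show that under these noise and
texture conditions the similarity metric's own optimum lies ≈ 0.7 mm from
the truth with a Jacobian rank correlation of ≈ 0.87, and that gradient
refinement from any reachable starting point converges to a distinct, worse
attractor family. The voxelwise Jacobian *ranking* is therefore noticeably
noisier than the displacement field itself; downstream statistics that
aggregate over sections (the functional-ratio tables, the position
contrasts, the DVF orientation indices) are robust to this and reproduce
all expected position-dependent patterns, but voxel-level Jacobian values
from registered fields should be read with this uncertainty in mind.

## Sections, volumes and statistics

Anatomical landmarks (aortic arch, carina, heart, diaphragm dome) do not
exist on a phantom, so the four sections are axial slabs centred at fixed
fractions of the apex-to-base extent (0.15, 0.40, 0.65, 0.88), three slices
thick by default; a thickness of 1 restores literal single-slice sections.
Lung segmentation is a −400 HU threshold followed by removal of
border-connected air, retention of the two largest components, and
left/right labelling by centroid (with a mid-sagittal split if the lungs
fuse). Volumes are voxel counts times voxel volume.

The Wilcoxon signed-rank test drops zero differences, uses mid-ranks on
tied magnitudes, and computes the exact two-sided p-value by subset-sum
convolution over all 2^n sign assignments for n ≤ 25 (identical to full
enumeration), switching to a tie- and continuity-corrected normal
approximation above. The Bonferroni threshold is kept at full precision
internally and *truncated* (not rounded) to three decimals for display, so
0.05/3 displays as 0.016.

Cohort simulation draws per-subject offsets on the global expansion
(SD 0.04, clamped to the deformation range every position supports) and the
gravity gradient (SD 0.02), shared across positions so the comparison is
paired, with independent rendering noise per scan.

## Numerical choices and degenerate inputs

* Finite differences for the Jacobian are central in the grid interior and
  one-sided on the boundary, each divided by the physical spacing of its
  axis; grids need at least 3 voxels per axis.
* Percentile ranks use the mid-rank convention; `functional_mask` applies a
  strict `rank >= threshold` rule, so constant maps flag nothing.
* The phantom generator refuses specifications whose ground-truth
  deformation folds (numerical Jacobian ≤ 0.01 anywhere in the body) and
  lungs that leave the untapered core of the body.
* Out-of-domain samples in `warp` take ambient air HU (−1000); the
  registration metric instead samples with coordinate clamping, because a
  fill-value jump at the grid faces would create a spurious discontinuity
  at zero displacement.
* All randomness (texture, noise, cohort jitter) flows through explicit
  integer seeds; registration and all analysis stages are deterministic.

## Problem sizes used in the validation suite

Unit and property tests run on 48³ phantoms at 4 mm spacing; the
registration-recovery check runs on the default 96³ grid at 2 mm, and the
position-pattern check on 64³ grids at 3 mm, all chosen so the full suite
completes in a few minutes on a single CPU while exercising the same code
paths as larger volumes.
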