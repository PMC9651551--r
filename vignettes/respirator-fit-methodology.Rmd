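---
title: "Respirator fit prediction by deformable surface registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respirator fit prediction by deformable surface registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respfit)
```

`respfit` quantifies the geometric fit of a tight-fitting respirator on an
individual face. This vignette is the package's own account of the method:
the model and its assumptions, the parameters that matter, what the
synthetic scenes do and do not emulate, the numerical choices, and the known
limitations.

## The estimation problem

The input is a set of triangulated surface meshes in millimetres: a
subject's face scanned without (`unloaded`) and with (`loaded`) the
respirator in situ, the respirator's whole geometry and internal surface,
and a reference head scanned with and without the respirator seated on it.
The quantity of interest is where, and over how much of its area, the
respirator's internal surface would sit relative to the skin: gapping from
it (air leakage), sealing against it, or indenting it enough to load the
soft tissue.

The core difficulty is that a filtering facepiece is flexible. A purely
rigid registration of its internal surface onto a face systematically
understates contact, so the method deforms the surface over a ladder of
stiffness levels and lets the data select how much deformation the real
device exhibited, by comparing against the loaded scan.

## Rigid registration

Rigid alignment is point-to-point iterative closest point (ICP): alternate
(i) matching every source vertex to its nearest target vertex and (ii) the
closed-form least-squares rigid fit (`kabsch_fit()`, SVD-based, reflections
excluded). The RMS correspondence distance is non-increasing across
iterations, and a `trim_fraction` option drops the worst matches each
iteration — useful when part of the source has no true counterpart
(scanning artefacts, partially overlapping surfaces).

Choices that matter:

* **Correspondence is vertex-to-vertex**, accelerated by a k-d tree
  (compiled; ties broken to the lowest reference index) whose output is
  required — and tested — to equal exhaustive search exactly. The distance
  summaries downstream are likewise vertex-based.
* **Initialisation is centroid alignment**, optionally disabled
  (`centroid_init = FALSE`). Disabling it is the right choice whenever the
  inputs are already in a common frame: re-centring a respirator patch
  against a whole face would throw the prior alignment away. The alignment
  cascade uses centroid initialisation; all post-cascade registrations do
  not.
* **Convergence defaults are `max_iterations = 300`,
  `rms_tolerance = 1e-7` mm.** Point-to-point ICP converges linearly, and
  on realistic face scenes a looser tolerance (say `1e-4`) halts inside the
  slow tail with the rotation still millimetres off; 100–200 iterations at
  `1e-7` is what the same scenes need to reach their minimum. These
  defaults trade a few seconds of compute for reliable convergence.

ICP is a local optimiser and stays one: no feature-based global
initialisation is attempted. Scans are expected to be pre-rotated to a
common "face along +z" convention (`pre_rotate()`), which is how the
acquisition pipeline this method targets prepares its meshes.

## The deformation ladder

Non-rigid ICP (`nonrigid_icp()`) follows a displacement-field formulation:
after a rigid alignment, each vertex is pulled toward its nearest target
vertex, the pull field is smoothed, a fraction of it is applied, and the
process repeats to convergence. One stiffness governs all vertices. The
deformation index k in 1..8 maps to a stiffness

> s(k) = 0.05 × 4^(k−1)

a geometric ladder spanning ~0.05 (nearly unconstrained) to ~819 (nearly
rigid). The stiffness enters three ways: the applied step is
`1/(1+s)`, the Laplacian blend is `s/(1+s)`, and the smoothing pass count is
`ceiling(log2(1+s))`. What is *contractual* — and what the tests pin down —
is the behaviour at the ends and the ordering in between:

* at k = 1 the deformed surface tracks the target to a mean absolute signed
  distance below 0.2 mm on smooth scenes;
* at k = 8 the result deviates from the plain rigid answer by less than
  0.5 mm mean vertex displacement;
* conformity (see below) is monotone non-increasing in k up to a 1
  percentage-point slack;
* the `rigid` level is bit-identical to `icp_align()` + `apply_transform()`.

Any smoothing/step schedule meeting that contract would be equally valid;
the analysis downstream consumes only the resulting distance distributions.
The iteration stops when the largest per-iteration vertex motion falls
below 0.01 mm, or at 50 iterations. There is no randomness anywhere in
registration, so identical inputs give identical outputs bit for bit.

Laplacian smoothing (`laplacian_smooth_field()`) replaces each vertex's
displacement with a blend of itself and its topological neighbours' mean;
constant fields are fixed points, isolated vertices are untouched, and each
pass is non-expansive in the field's Dirichlet energy for blends in [0, 1]
(smoothing can only even out the field, never roughen it).

## Distances, bands, and the optimum

`signed_distances()` assigns every respirator vertex the distance to its
nearest face vertex, signed by the side of the face surface it lies on
(outward normal positive: a gap; inward negative: indentation). Weights are
the per-vertex share of the respirator surface area (a third of each
incident triangle), so percentages read as *percentage of respirator area*;
uniform vertex-count weighting is available for sensitivity checks.

`summarize_distances()` reports the central 95% interval of the weighted
distribution — its bounds are the 2.5th/97.5th weighted percentiles
(midpoint-rule empirical CDF with linear interpolation) — plus a
density-normalised histogram. The interval *width* is the scalar used to
compare deformation levels: a respirator tracking the face tightly has a
narrow distance distribution.

`gof_metrics()` scores three bands that partition the area exactly:
gap (d > 0), adequate seal (−3 ≤ d ≤ 0) and substantial indentation
(d < −3 mm), the −3 mm threshold being the conventional soft-tissue
tolerance for sustained loading; boundary values follow the stated
inequalities exactly (0 and −3 count as seal). Conformity is the inclusive
band |d| ≤ 1 mm.

`select_delta_optimum()` operationalises "high conformity, tight
distribution" as: argmax conformity; ties within 0.05 pp resolved by the
smaller interval width; remaining ties by the stiffer level (rigid counting
as stiffest, on the grounds that claiming less deformation is the more
conservative fit prediction). Applied to a printed nine-level conformity
column this reduces to picking the column maximum, which is exactly how the
published per-participant sweep table is annotated.

Soft-tissue displacement (`tissue_displacement()`) registers the loaded
face to the unloaded face and summarises the signed distances of the loaded
vertices; its default settings trim 20% of correspondences so the alignment
locks onto the undeformed majority of the face instead of averaging over
the indented and bulged regions.

## The synthetic scenes

No scan data are redistributable, so `make_scene()` generates the full
six-mesh scene with ground truth:

* **Face**: a height field z = f(x, y) — smooth dome + Gaussian nose ridge
  + two cheek mounds — triangulated over a 140 × 180 mm patch at 80 × 80
  vertices by default (the full pipeline then runs in seconds on one CPU;
  tests use 40–80). Interior sample points carry a deterministic
  quasi-random jitter of 0.3 cells: real scan meshes are irregular, and a
  perfectly regular grid is also a degenerate input for vertex-based ICP —
  it offers a lattice of translational quasi-minima in which the iteration
  can stall. Landmarks are placed analytically on the surface.
* **Respirator**: the internal surface is the nose/mouth region of the face
  offset along its vertex normals (default +2 mm, i.e. slightly gapped)
  with a rim band tapering to skin contact — an idealised "as worn" shell.
  The whole geometry adds an outer cup whose dome rises 12 mm over the
  region centre, matching the semi-rigid dome of a real FFP3 shell and
  giving the scan a registration-friendly distinctive shape.
* **Loaded face**: the unloaded face displaced along its normals by a
  prescribed field — an indentation plateau (default 5 mm deep) under the
  lower rim and lateral bulge plateaus (default 4 mm) on the cheeks, both
  with cosine falloffs and plateaus covering comfortably more than 2.5% of
  the face area so that the 2.5th/97.5th percentiles of the prescribed
  field sit at the prescribed extremes. These analytic percentiles are
  recorded as ground truth *from the field itself*, never from any
  registration output. Optional Gaussian vertex noise is seeded and
  reproducible.
* **Reference head**: the canonical unperturbed face; the
  head-with-respirator reference is that face with the respirator seated,
  the covered skin occluded as a surface scan would show it. Subject meshes
  are displaced by a known rigid perturbation (default 8° about a skew axis
  plus ~11 mm), which the alignment cascade must recover.

What the scenes deliberately do **not** emulate: real anthropometric
variation between faces, undercuts or self-occlusion (a height field keeps
every signed distance unambiguous), scanning noise correlated along the
surface, holes and topological defects, and any material mechanics of the
respirator. Passing tests on these scenes therefore demonstrates that the
*algorithms* behave as specified — transform recovery, band accounting,
percentile recovery, ladder ordering — not that predictions on real faces
are accurate; that corroboration requires imaging, and in the cohort study
this method derives from it was done with MRI.

## Numerical choices and degenerate inputs

* STL welding tolerance 1e-6 mm (STL duplicates shared vertices per facet;
  welding restores connectivity). Units are millimetres by convention — STL
  has no unit metadata.
* Mesh cleaning drops exact duplicate faces, zero-area faces, connected
  components below 1% of the largest component's area (segmentation
  debris), and unreferenced vertices; cleaning is idempotent, and cleaning
  everything away is an error rather than an empty mesh.
* Nearest-neighbour ties: lowest reference index, in both the k-d tree and
  the exhaustive oracle, so results are order-independent and the two
  search paths are bit-identical.
* Kabsch degeneracy: nearly collinear point sets raise a
  singular-configuration error instead of returning an arbitrary rotation.
* ICP non-convergence is reported (`converged = FALSE`), not thrown; the
  command-line front end escalates it to a failure only under `--strict`.
* Percentile edge cases: a constant distance distribution has interval
  width exactly 0; histogram bins default to 100 over the data range.
* The conformity tie tolerance (0.05 pp) matches the precision of printed
  conformity tables, so re-running the selection on a rounded table cannot
  invent spurious ties.

## Design decisions on open points

* The published description names five facial anthropometrics but defines
  four; the package implements the four defined ones (bio-ocular width,
  alar width, dorsal nasal length, lower-third facial height).
  Lower-third height is measured subnasale→menton surrogate because facial
  scans in this workflow rarely include the full facial height.
* Whether the original distance histograms were area- or vertex-weighted is
  not stated; area weighting is the default here (the reported quantity is
  a *percentage of respirator area*), with count weighting as an option.
* The "95% CI" of a distance distribution is taken as the width of the
  central interval containing 95% of the weighted distances — the only
  scalar consistent with reporting a single CI value per registration.
* Distances are vertex-to-vertex rather than point-to-surface; at the mesh
  resolutions used the difference is below the band widths, and it keeps
  the accelerated search exactly checkable against brute force.

## Limitations

All respirator vertices share one stiffness per level: the method cannot
represent a shell that is stiff at the nose clip and soft at the chin. The
ladder's stiffness values are a modelling convention — only the ordering
and its two ends are identifiable from fit data. ICP is local: scans must
be roughly pre-oriented (the standard 90° pre-rotation convention), and
pathological inputs (near-symmetric smooth surfaces, regular lattices) can
still stall it. Fit is assessed purely geometrically — no contact
mechanics, no strap tension, no breathing cycle — and the goodness-of-fit
bands are a screening quantity, not a substitute for a quantitative fit
test.
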