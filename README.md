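# respfit

Predicting how well a filtering facepiece respirator (FFP3/N95 class) fits an
individual face, from 3D surface scans alone.

Tight-fitting respirators only protect when they seal around the nose and
mouth, but commercial devices come in a narrow range of shapes and sizes and
fit poorly on many faces. `respfit` implements a registration-based fitting
methodology for quantifying that mismatch geometrically: the internal surface
of a respirator is aligned to a facial scan, deformed over a ladder of
stiffness levels, and scored by how much of its area gaps from the skin,
seals against it, or indents it. The package is aimed at researchers in
medical-device fit, facial anthropometry and surface-scan analysis.

## Method

All meshes are triangulated surfaces in millimetres (binary or ASCII STL).
The pipeline is:

1. **Alignment cascade** — the subject's unloaded (no respirator) and loaded
   (respirator in situ) facial scans are rigidly aligned to a common
   reference head by iterative closest point (ICP: alternate
   nearest-neighbour correspondence with the closed-form Kabsch rigid fit);
   the respirator whole geometry is aligned to a reference scan of the head
   with the respirator in situ, and that transform carries the respirator's
   internal surface into the same frame.
2. **Stiffness-laddered deformation** — the internal surface is deformed
   toward the unloaded face by non-rigid ICP: per-vertex closest-point pull
   regularised by Laplacian smoothing whose strength follows a stiffness
   ladder δ1..δ8 (δ1 nearly free, conforming closely; δ8 near rigid), plus a
   pure-rigid level.
3. **Distance scoring** — after rigid registration onto the loaded face,
   each respirator vertex gets a signed distance to its nearest face vertex
   (positive = gap, negative = indentation), area-weighted. Per level the
   method records the conformity (% of respirator area with |d| ≤ 1 mm) and
   the width of the central 95% interval of the distance distribution.
4. **δ-optimum selection** — the level with maximal conformity wins; ties
   (within 0.05 pp) go to the tighter distribution, then to the stiffer
   level. The respirator is then deformed at the optimum onto the unloaded
   face and scored into goodness-of-fit bands: gap (d > 0), adequate seal
   (−3 ≤ d ≤ 0) and substantial indentation (d < −3 mm).
5. **Soft-tissue displacement** — the loaded face is registered to the
   unloaded face; the 2.5th/97.5th percentiles of the signed distances give
   the negative (indentation) and positive (bulge) tissue displacement.
6. **Anthropometrics** — landmark distances (bio-ocular width, alar width,
   dorsal nasal length, lower-third facial height) are correlated with the
   goodness-of-fit percentages (Shapiro–Wilk, then Pearson, α = 0.05).

Because no scan data ship with the package, a deterministic synthetic scene
generator (`make_scene()`) builds face/respirator/loaded-face scenes with
analytic ground truth (known rigid misalignments, prescribed indentation and
bulge fields, exact landmarks) against which every stage is tested.

## Worked example

```r
library(respfit)
scene <- make_scene(scene_params(seed = 1))
fit <- respirator_fit(scene$unloaded_face, scene$loaded_face,
                      scene$respirator_whole, scene$respirator_internal,
                      scene$reference_head, scene$reference_head_with_respirator)
summary(fit)
```

```
respirator_fit
  optimum level: delta5 (conformity 68.3%)
  predicted fit: seal 25.4%, gap 74.6%, indentation 0.0%
  soft-tissue displacement: -5.00 / 4.00 mm

sweep table:
  level pct_conform ci_width pct_gap pct_seal pct_indent
 delta1       68.09    5.359   46.51    53.11     0.3825
 delta2       68.09    5.359   46.51    53.11     0.3825
 delta3       68.09    5.357   46.51    53.11     0.3825
 delta4       68.14    5.352   46.29    53.33     0.3809
 delta5       68.30    5.448   47.74    51.83     0.4281
 delta6       67.14    5.979   53.96    45.34     0.7065
 delta7       45.31    6.703   60.30    37.62     2.0742
 delta8       45.25    6.707   60.30    37.62     2.0743
  rigid       45.25    6.708   60.30    37.62     2.0743
```

Reading the output: conformity to the loaded face is highest (68.3%) at the
interior level δ5 and collapses toward the rigid end (45.3%), which is also
the loosest distribution (interval width 6.7 mm) — deformability clearly
improves the predicted fit. The recovered soft-tissue displacement
(−5.00 / +4.00 mm) matches this scene's prescribed indentation depth (5 mm)
and lateral bulge (4 mm) exactly. In the final fit at δ5 the respirator sits
just proud of the skin over most of its area, so that area counts as gap
(d > 0) even though 68% of it is within 1 mm of the face; on this synthetic
template only a quarter of the area touches into the seal band.
`plot(fit)` draws conformity and interval width against the ladder;
`coef(fit)`, `predict(fit, level)` and `residuals(fit)` expose the numbers.

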