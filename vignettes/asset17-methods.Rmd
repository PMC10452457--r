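---
title: "Methods: automatic AHA 17-segment modeling of the left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic AHA 17-segment modeling of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radio-ablation of ventricular tachycardia needs the arrhythmogenic substrate
localized on the radiotherapy planning CT. Electro-anatomic mapping data
cannot be registered to the planning image directly, so clinical practice
localizes the target through the American Heart Association (AHA) 17-segment
model of the left-ventricular myocardium (LVM): 6 basal, 6 mid-cavitary and
4 apical segments plus the apex cap, each with a canonical anatomical name.
Drawing those 17 segments by hand takes hours per patient and is highly
observer-dependent. `asset17` generates them automatically from two manual
inputs: a binary left-ventricle (LV) mask and a single right-ventricle (RV)
insertion point.

## The model

**Long axis.** The parasternal long axis (PLAX) is estimated as the first
principal component of the physical-mm coordinates of all LV mask voxel
centers — the eigenvector of their covariance matrix with the largest
eigenvalue, anchored at the mask centroid. PCA is run on the full solid
mask, not a surface extraction; whether a surface-point PCA would behave
differently on strongly asymmetric walls is untested here (deliberately not
guessed). The eigendecomposition is declared ambiguous, and refused, when
the two largest eigenvalues agree within a relative 1e-6 (a sphere has no
major axis). The eigenvector sign is resolved by pointing the axis at the
narrow end: the extent end whose average cross-sectional area over the
terminal 10% of the axial extent is smaller is taken as the apex, mirroring
the manual basal-then-apical point convention. Ends tying within 1% raise an
error that the caller can override (`force_orientation`).

**Myocardium.** The LVM is standardized to an 8 mm wall: the cavity is the
erosion of the LV mask by a Euclidean ball of 8 mm and the shell is the
remainder. Erosion is realized through an exact anisotropic Euclidean
distance transform in mm (voxels whose distance to background is at least
the thickness), so a 1 × 1 × 1.5 mm CT grid erodes by physical millimeters,
not voxel counts. The "8 mm" is therefore operationalized as distance from
the epicardial *voxel* boundary; for oblique walls there is no other
published definition to follow. Where the cavity reaches the image edge
(a mask curated by cutting at the mitral-valve plane) the base stays open;
an optional plane cut perpendicular to the axis (`basal_cut`) reproduces the
manual mitral-valve removal when the input is not curated.

**Regions.** Three short-axis planes split the shell into basal, mid,
apical, and apex regions. The basal extent `t0` and apex tip `t4` are the
extreme axial coordinates of shell voxels. The apex region starts at the
endocardial cavity tip (`t3` = maximal axial coordinate of cavity voxels),
the standard "no-cavity cap" convention; a fixed fraction of the extent is
available as an override, and the choice is recorded in the result. `t1`
and `t2` trisect `[t0, t3]`, making the three named regions exactly equal in
axial span.

**Sectors.** Azimuth 0 is the direction from the axis to the RV insertion
point; only the point's azimuth matters, not its axial position. Positive
azimuth follows the right-hand rule about the base-to-apex direction, so
increasing azimuth runs anterior → anterolateral → … → anteroseptal. That
chirality is forced by internal consistency: the apical ring's boundaries
sit at −15°/75°/165°/255°, and the apical anterior segment [−15°, 75°) is
concentric with the basal/mid anterior sector only if the anterior sector is
[0°, 60°). Datasets whose anatomy disagrees can set `flip_rotation`. Basal
and mid rings use six 60° sectors (labels in azimuth order: 1, 6, 5, 4, 3, 2
and 7, 12, 11, 10, 9, 8), the apical ring four 90° sectors
(13, 16, 15, 14); the apex cap is label 17 at any azimuth.

**Boundary handling.** All angular and axial intervals are closed-left /
open-right, the last axial interval closed. Classification adds a 1e-9
nudge before the comparisons so a voxel lying exactly on a plane or sector
boundary classifies deterministically and does not flip under rigid motion
of the coordinate frame (rotating an affine perturbs dot products at the
1e-11 level; the nudge dominates). Voxels are classified by their center
coordinate; there is no sub-voxel polygon clipping.

**Closing.** In the default voxel mode every shell voxel is labeled
directly, then each segment is morphologically closed (dilation followed by
erosion) with a Euclidean ball of 2 mm and re-intersected with the shell.
The structuring element is not specified by any published source, so a small
isotropic ball was chosen; voxels claimed by several closed segments, or by
none, keep their pre-closing label, which keeps the output an exact
partition of the shell. The `surface_closing` mode reproduces the variant in
which only endocardial and epicardial surface voxels are assigned and
closing fills the wall: there the ball radius defaults to half the wall
thickness plus half a voxel diagonal (the smallest ball that bridges the two
labeled surfaces), and mid-wall wedges at sector boundaries that no closed
segment reaches — the closing ball necessarily crosses into the neighbor's
territory there — are assigned to the nearest labeled surface voxel, as are
multi-claim voxels, so the partition survives.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `thickness_mm` | 8 | mm | standardized LVM wall when contrast cannot resolve the endocardium |
| `apex_rule` | `cavity_tip` | — | apex = shell distal to the cavity tip; fraction override available |
| `closing_radius_mm` | 2 | mm | smooths jagged sector faces without moving anatomy |
| `mode` | `voxel` | — | direct labeling; `surface_closing` mirrors the surface-assignment workflow |
| `flip_rotation` | `FALSE` | — | azimuth chirality for atypical anatomies |
| `mda_step_mm` | 1 | mm | sampling step for axis mean-distance comparison |

## The phantom: what it emulates, what it does not

The test bed replacing unavailable patient CTs is a half prolate spheroid:
epicardium with a 90 mm long axis and 40 mm basal radius, open at the flat
basal plane; endocardium the true perpendicular inward offset of that
surface by the 8 mm wall (computed by exact point-to-ellipse distance in the
axisymmetric plane), cavity open at the base, apex cap solid. The grid is
1 × 1 × 1.5 mm, matching thoracic CT; in-plane voxel centers are laid out
symmetrically about the axis (no voxel sits exactly on it) and the field of
view is cropped exactly at the basal plane, emulating a curated clinical
mask — that crop is what keeps the cavity open under the distance-transform
erosion, the role the manual mitral-valve removal plays clinically. The RV
insertion point sits on the epicardial surface at mid-level, azimuth 0 by
default. Optional uniform sub-voxel surface jitter (seeded) supports
robustness tests and is off by default.

The analytic truth labels are produced by an independent oracle: each voxel
is labeled in closed form from its cylindrical coordinates about the *true*
axis, with its own copies of the region/sector arithmetic — no PCA, no
morphology, no shared assignment code — so pipeline-vs-oracle agreement is
evidential.

Two things the phantom does not have: image intensities (no CT contrast,
ICD artifacts or motion), and wall-thickness variation — so a green suite
establishes geometric correctness of the construction, not clinical
performance on real anatomy. One measurement subtlety follows from the dual
endocardium definitions: the pipeline's cavity is "≥ 8 mm from background
voxel centers", the truth's is "≥ 8 mm from the continuous epicardial
surface". These agree only up to voxel discretization, leaving a sub-voxel
endocardial ring (~2–3% of shell volume, support Dice ≈ 0.986 on the default
phantom) on which the two shells disagree about membership, not about
labels. The oracle-agreement criterion is therefore asserted on the common
support — voxels both maps call myocardium — where measured agreement is
1.000; per-segment Dice against truth (0.976–0.997) absorbs the support
ring.

## Numerical choices

- Distances are exact Euclidean distance transforms (separable
  lower-envelope algorithm in C++), anisotropy handled by physical spacing;
  no chamfer approximations.
- The mean distance to agreement is boundary-voxel-center to
  boundary-voxel-center (6-connectivity boundary, array edges count as
  background), symmetric: the average of the two directed means. Reported
  millimeter values are reproducible bit for bit; they are not sub-voxel
  mesh distances.
- The axis mean distance samples each segment every 1 mm within its own
  extent against the other *infinite* line, and averages the two directed
  means; the angle between undirected lines is folded to [0°, 90°].
- Segment averages are unweighted across segments (each of the 17 counts
  equally).
- Dice of two empty masks is defined as 1, with a warning; a segment
  present in only one map scores Dice 0 and a flagged, undefined MDA.
- Eigen-decomposition, erosion and closing are deterministic; the only
  randomness anywhere is the phantom's optional jitter and test/report
  sampling, all seeded.

## Known limitations

- No automatic LV segmentation: the mask and RV point are inputs by design.
- The RV insertion point must be off-axis; its axial position is ignored.
- DICOM RT-STRUCT import is not implemented in this version; NIfTI is the
  canonical volume format (the package carries its own minimal NIfTI-1
  codec, validated against nibabel).
- Segments can legitimately be empty on pathological masks; that produces a
  warning, not an error, and the sidecar table records zero voxels.
- The apical ring's registration at −15°/75° follows the consistency
  argument above; a site preferring a different apical registration would
  need to adjust the sector tables.
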