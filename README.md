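# asset17

Automatic generation of the American Heart Association (AHA) 17-segment
model of the left-ventricular myocardium (LVM) from a 3D binary
left-ventricle (LV) mask and a single right-ventricle (RV) insertion point.

## Who this is for

Radiotherapy planning for ventricular-tachycardia radio-ablation (and any
other workflow that localizes myocardial targets by AHA segment) needs the
17 segments drawn on the planning CT. Manual delineation takes hours per
patient with large inter-observer variability; this package automates
everything after the two quick manual inputs.

## The method

Given an LV mask `M` (NIfTI, with its voxel-to-mm affine) and an RV
insertion point `p_RV` (mm):

1. **Long axis** — the parasternal long axis is the first principal
   component of the mask voxel coordinates: the eigenvector `v₁` of
   `Cov{x : x ∈ M}` with the largest eigenvalue, anchored at the centroid
   and oriented base → apex (apex = the narrow end).
2. **Myocardium** — the wall is standardized to 8 mm: cavity
   `C = {x ∈ M : dist(x, Mᶜ) ≥ 8 mm}` by exact anisotropic Euclidean
   distance transform; shell `W = M \ C`.
3. **Regions** — three short-axis planes perpendicular to the axis split
   `W` into basal, mid, apical (equal axial spans over base → cavity tip)
   and apex (distal to the cavity tip).
4. **Sectors** — azimuth 0 points at `p_RV`; basal/mid rings get six 60°
   sectors, the apical ring four 90° sectors with boundaries at
   −15°/75°/165°/255°, the apex cap is segment 17.
5. **Closing** — each segment is morphologically closed (2 mm ball) and
   the partition of `W` restored.

Evaluation metrics (Dice similarity coefficient and symmetric mean distance
to agreement, per segment and averaged), a prolate-spheroid phantom with an
independent analytic ground truth, minimal NIfTI-1 I/O, and a CLI are
included. See `vignettes/asset17-methods.Rmd` for the full account.

## Worked example

```r
library(asset17)

ph  <- make_lv_phantom()                    # synthetic LV + truth labels
res <- run_asset(ph$lv_mask, ph$rv_point)   # the full pipeline

res$axis
#> <lv_axis> anchor (0.00, 0.00, 33.75) mm, direction (-0.0000, -0.0000, 1.0000), extent [-33.00, 55.50] mm
res$planes
#> <region_planes> t0..t4 = -33.00 | -6.00 | 21.00 | 48.00 | 55.50 mm
res
#> <segmentation_result> mode voxel, 84140 labeled voxels, 17 distinct segments

evaluate_pair(res$labels, ph$truth_labels)
#> <segment_metrics> 17 segments: DSC 0.987 +/- 0.005, MDA 0.071 +/- 0.028 mm

head(segment_report_table(res), 4)
#>   label               name region theta_lo theta_hi voxels
#> 1     1     basal anterior  basal        0       60   5194
#> 2     2 basal anteroseptal  basal      300      360   5194
#> 3     3 basal inferoseptal  basal      240      300   5096
#> 4     4     basal inferior  basal      180      240   5194
```

Reading the numbers: the recovered long axis is the phantom's true axis
(straight up the z of the grid, anchored at the centroid 33.75 mm above the
basal plane); the region planes sit at equal 27 mm spans from the base
(t = −33) to the cavity tip (t = 48) with the apex cap beyond; all 17
segments are present and agree with the independent analytic truth at a
mean Dice of 0.987 and mean surface distance of 0.07 mm — residual
disagreement is the sub-voxel endocardial discretization ring discussed in
the vignette.

On real data, replace the phantom by your files:

```r
lv  <- read_mask("lv.nii.gz")
rv  <- read_point_file("rv.json")[1, ]
res <- run_asset(lv, rv, asset_config(thickness_mm = 8))
write_labels(res$labels, "segments.nii.gz")
```

## Command line

```sh
Rscript inst/cli/asset phantom --preset default -o ph/
Rscript inst/cli/asset segment --lv ph/lv.nii.gz --rv-point ph/rv.json \
        --physician-axis ph/axis.json -o seg/
Rscript inst/cli/asset evaluate --a seg/segments.nii.gz --b ph/truth.nii.gz -o report.csv
Rscript inst/cli/asset compare-axes --a seg/plax.json --b ph/axis.json
```

(after installation the script is at `system.file("cli", "asset", package = "asset17")`).

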