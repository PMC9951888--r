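# stentmorph

Rapid morphological measurement of thoracic aortic stent-grafts across
follow-up CT scans.

After thoracic endovascular aortic repair (TEVAR) for type B aortic
dissection, the stent-graft keeps moving and deforming as the aorta
remodels. `stentmorph` quantifies that change without full manual 3-D
reconstruction: it reduces each scan to the peak (apex) points of every
zig-zag support ring, registers those observation points to a skeletal
landmark (the 12th thoracic vertebra in clinical use), and computes three
parameter families as combinatorial functions of the registered points:

- **End-slip vector** — componentwise displacement of an end ring's midpoint
  between periods *i* and *j*: `Δ_ij = P_Oi − P_Oj` (mm), with
  `point_mid = (1/N) Σ_j P_j`.
- **Characteristic diameter and ring rate** — `ρ = max_{i<j} |P_i P_j|` and
  `R_k = (ρ_k / ρ_1)²` (dimensionless, `R_1 = 1`), the ring's relative
  radial deformation versus baseline.
- **Ring deflection angle** —
  `α_j = arcsin(((OP_j × OP_j′) / (|OP_j||OP_j′|)) · n̂)`, `β = mean(α_j)`
  (degrees), with `n̂` along the baseline ring-midpoint direction
  `O_{k+1} → O_k` as the ring-plane normal approximation.

Upstream of that, the package provides classical HU-threshold stent
segmentation ([1200, 2200] band, connectivity-based region selection, Dice
QC), 26-connected support-ring separation, a cubic-spline centerline through
ring centroids, and a fully automatic, deterministic apex extractor
(per-sector axial extrema → amplitude filter + non-maximum suppression →
2 mm sphere clustering). Because the clinical cohort it emulates is not
publicly available, a parametric voxel phantom with analytic apex ground
truth (zig-zag rings, 1 mm grids, CT-like HU compartments, seeded noise,
replayable translate/scale/twist/bend deformations) makes every stage
testable end-to-end. See `vignettes/stent-morphometry.Rmd` for the full
methods account.

## Worked example

Generate a 3-ring phantom, impose a follow-up deformation (translation
(3, −2, 5) mm + radial scale 1.25 + twist 10°), and measure it through the
full voxel pipeline:

```r
library(stentmorph)

spec <- phantom_spec(n_rings = 3)          # R = 15 mm, A = 7.5 mm, 1 mm grid
st1  <- generate_stent(spec)
st2  <- apply_deformation(st1, deformation("translate", c(3, -2, 5)))
st2  <- apply_deformation(st2, deformation("radial_scale", 1.25))
st2  <- apply_deformation(st2, deformation("twist", 10))

p1 <- register_to_origin(extract_peaks(voxelize(st1), timepoint = "T1"))
p2 <- register_to_origin(extract_peaks(voxelize(st2), timepoint = "T2"))

compare_point_sets(p1, ground_truth_points(st1))
#> <extraction_agreement> 15/15 matched (missing 0.0%), D mean 0.317 mm, D max 0.418 mm

rep_ <- measure_series(list(p1, p2))
rep_$slip[rep_$slip$end == "proximal", c("dx_mm", "dy_mm", "dz_mm")]
#>   dx_mm dy_mm dz_mm
#> 1 -2.90  2.05 -5.00        # slip = P_O(T1) − P_O(T2) ≈ −(3, −2, 5)
rep_$diameter$ring_rate[rep_$diameter$timepoint == "T2"]
#> [1] 1.5539 1.5539 1.5539   # imposed 1.25² = 1.5625
rep_$deflection$beta
#> [1] 10.146 10.146 10.146   # imposed 10°
```

All imposed deformations are recovered at voxel accuracy: translation within
0.1 mm/component, ring rate within 1%, twist within 0.2°. The printed values
above are exactly what the code produces (they are recomputed by
`scripts/acceptance.R` and by the test suite).

## Command line

```sh
stentmorph phantom --rings 7 --apices 5 --deform translate=3,0,0@T2 --out phantom/
stentmorph segment --in ct.nii.gz --lo 1200 --hi 2200 --mode largest --out mask.nii.gz
stentmorph rings   --mask mask.nii.gz --min-volume 50 --out rings.json
stentmorph peaks   --mask mask.nii.gz --orientation proximal --out peaks.csv
stentmorph compare --a auto.csv --b manual.csv --threshold 5
stentmorph measure --points t1.csv,t2.csv --out report.json
stentmorph run     --manifest case.json --out out/
```

The wrapper script is `inst/scripts/stentmorph` (or call
`stentmorph::stentmorph_cli()` from `Rscript`). Exit codes: 0 success,
2 validation error, 3 stage failure.

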