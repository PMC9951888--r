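---
title: "Rapid morphometry of thoracic stent-grafts: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid morphometry of thoracic stent-grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentmorph)
```

## The measurement problem

After thoracic endovascular aortic repair (TEVAR), the implanted stent-graft
keeps moving and deforming as the dissected aorta remodels. Quantifying that
change across follow-up CT scans — how far the ends have slipped, how much
each support ring has expanded or been compressed, how much each ring has
rotated about the vessel axis — normally requires slow manual 3-D
reconstruction. `stentmorph` implements a rapid alternative: reduce each scan
to a small, *non-divisible* set of observation points (the apices of every
zig-zag support ring), register those points to a fixed skeletal landmark,
and express all morphological change as combinatorial functions of the
registered points.

The pipeline is, per timepoint:

1. **Segmentation.** Stent metal is far denser than contrast-filled blood
   (vessel ≈ 300–700 HU). Voxels within the HU band [1200, 2200] are kept
   (lower bound excludes contrast, upper bound suppresses blooming
   artifacts), then connectivity-based region selection removes speckle.
   Volumes are first resampled to 1 mm isotropic spacing.
2. **Ring separation.** 26-connected component labeling splits the mask into
   support rings; components under a volume threshold are dropped.
3. **Centerline.** Ring voxel-mass centroids, ordered proximal→distal, are
   interpolated by a natural cubic spline with chord-length
   parameterization.
4. **Peak extraction.** Per ring, apex candidates are the per-sector axial
   extrema in the local centerline frame, filtered and merged (details
   below).
5. **Registration.** All coordinates are translated by minus the skeletal
   origin landmark (placed on the 12th thoracic vertebra in clinical use),
   so timepoints share one frame. Registration is a pure translation — a
   single bony point fixes three degrees of freedom; rotational correction
   is out of scope.

## The three parameter families

Let $P_{j}$ be the peak points of a ring and
$\mathrm{point\_mid} = \tfrac1N \sum_j P_j$ its midpoint.

**End-slip vector.** For the end ring's midpoints $P_{O_i}$, $P_{O_j}$ in
periods $i < j$,
$\Delta_{ij} = P_{O_i} - P_{O_j}$, reported per component (mm). It is
antisymmetric under period swap.

**Characteristic diameter and ring rate.** In-vivo rings are not regular
polygons, so ring size is summarized by
$\rho = \max_{i<j} \lVert P_i P_j\rVert$ and relative radial deformation by
the ring rate $R_k = (\rho_k / \rho_1)^2$ against the first period
($R_1 = 1$).

**Deflection angle.** With both periods' peaks recentered so their midpoints
coincide at $O$, and $\hat n$ the unit vector along $O_{k+1} \to O_k$
(consecutive ring midpoints of the baseline period, used as the ring-plane
normal approximation; the peaks need not be coplanar),
$$\alpha_j = \arcsin\!\Big(\frac{\overrightarrow{OP_j} \times
\overrightarrow{OP_j'}}{|OP_j|\,|OP_j'|} \cdot \hat n\Big), \qquad
\beta = \frac1N \sum_j \alpha_j .$$
For the most distal ring $M$ there is no ring $M+1$; the direction
$O_{M-1}\to O_M$ is negated and reused so $\hat n$ always points proximal.
The $\arcsin$ argument is clamped to $[-1, 1]$ with tolerance $10^{-9}$
(float excess only; larger excess errors out). Angles are reported in
degrees by default.

**Peak correspondence.** The deflection formula needs $P_j \leftrightarrow
P_j'$ pairs. Peaks are sorted by angular coordinate in the plane
perpendicular to $\hat n$ and matched by rank — deterministic, and correct
for twists below half the inter-peak angle (36° for a five-apex ring).
Unequal peak counts skip the ring with a warning rather than guessing.

**Method agreement.** `method_agreement()` reports mean and sample SD
(n−1) of paired differences and $R^2$ as the squared Pearson correlation
(a convention; the clinical source tables do not define $R^2$). Zero-variance
series are flagged degenerate instead of reporting a misleading 0. The
"relative error" output is $\mathrm{mean}(|a-b|)/\mathrm{mean}(|a|)$ —
likewise a labeled convention.

## Peak extraction in detail

Per ring, every foreground voxel gets cylindrical coordinates in the local
centerline frame: axial $s = (p - O)\cdot \hat t_{prox}$ (signed mm toward
the proximal end) and angle $\theta$ in the ring plane. The ring is divided
into `n_sectors` = 72 sectors (5°) and each sector's voxel of maximal $s$
(proximal side) or minimal $s$ (distal side) becomes a candidate, refined to
the centroid of the sector's extremal voxel layer (within half a voxel of
the extremum) for sub-voxel localization.

Candidate elimination has three parts:

* **Amplitude fraction** (`amp_fraction` = 0.6): candidates with $|s| <
  0.6\,\max|s|$ are eliminated — they sit on zig-zag flanks, not apices.
* **Absolute floor** (`min_amplitude_mm` = 2.0): a ring whose total axial
  amplitude is below 2 mm has no apices at all (a circular wire ring), yet a
  fraction-of-max filter alone would always retain its maximum. 2 mm is well
  below any clinically plausible apex amplitude and above wire thickness.
* **Non-maximum suppression** (`nms_window` = 2 sectors): only candidates
  that are axial local maxima within ±2 sectors survive. Without this step
  the amplitude filter leaves a chain of flank candidates with $s \in
  [0.6A, A]$ whose cluster mean sits roughly $0.2A$ (≈1.5 mm at the default
  7.5 mm amplitude) below the true apex — a systematic bias that would
  exceed the 1 mm accuracy the method is designed for. Suppression leaves
  only the one or two near-tied top candidates per apex, which the
  clustering step merges to their midpoint.

Setting `amp_fraction = 0` disables all elimination (one candidate per
occupied sector), which is useful for inspecting raw sector extrema.

Surviving candidates are expanded to 2 mm spheres; candidates whose spheres
touch (center distance ≤ 4 mm) merge transitively and each group collapses
to its arithmetic mean. Clustering is applied per ring and per orientation —
merging across rings would corrupt ring indexing, and proximal/distal apices
are separated by twice the apex amplitude anyway.

Extraction is fully deterministic (no RNG anywhere in the path) and
translation-equivariant: shifting the volume origin shifts every peak
exactly.

**Extraction QC.** `compare_point_sets()` scores an extracted set against a
reference by greedy one-to-one nearest-neighbor matching in ascending
distance order. Greedy (not Hungarian) matching is reproducible and adequate
at stent scales, where inter-peak spacing (≈19 mm for a five-apex ring of
15 mm radius) dwarfs extraction error (< 0.5 mm). A reference point with no
match within `match_threshold` = 5 mm counts as missing — 5 mm is below
half the minimum inter-apex distance of any plausible ring, and the
reported distances D are computed over matched pairs only. A separate
utility flags reader-pair disagreements over 1.5 mm for third-reader
adjudication, mirroring the manual annotation protocol.

## The phantom generator: what it emulates, what it does not

No patient data ship with the package (the clinical cohort it emulates is
withheld for ethical reasons), so a parametric phantom provides ground
truth. Each ring is the closed curve
$$C_r(\theta) = O_r + R(\cos\theta\, U + \sin\theta\, V) +
A\, z(N_p \theta)\, T$$
with $z$ a unit **triangle wave** — sharp extrema make the analytic apex
locations unambiguous (a sinusoid profile is available via
`profile = "sine"`). Each ring has exactly $N_p$ proximal and $N_p$ distal
apices, known in closed form. Defaults (`phantom_spec()`): 7 rings, 5 apices
per ring, radius 15 mm, apex amplitude 7.5 mm, ring spacing 22 mm, wire
radius 0.8 mm, 1 mm voxels — sized like a thoracic stent-graft and
resolvable at the 1 mm working resolution; 5–8 apices per ring covers the
devices' typical ring designs. Ring 1 is the most proximal (superior, +z)
ring, and the centerline can be straight or a circular arc.

Voxelization marks a voxel foreground iff its center lies within
`wire_radius` of any curve sample; curves are sampled at `grid_spacing/4` so
aliasing is bounded by a quarter voxel. CT synthesis paints stent voxels
(1700 HU default), a vessel-lumen tube (500 HU), and background (0 HU),
stent occluding vessel, plus seeded Gaussian noise.

Follow-up change is imposed kinematically and tracked exactly in the ground
truth: rigid `translate`, in-plane `radial_scale` about each ring's own
center, `twist` about the local centerline tangent (right-handed about the
proximal direction, so an imposed $+\theta$ is recovered as $\beta =
+\theta$), and rigid `bend` about an axis. Compositions are recorded and
replayable. Rings are generated *disjoint* (no connecting spine) to match
the connectivity-based ring separation step; a real stent-graft's fabric and
inter-ring struts are **not** modeled, nor are blood flow, tissue contact,
mechanical wire properties, imaging artifacts beyond Gaussian noise, or
DICOM geometry. A green phantom test therefore establishes that the
*algorithms* recover imposed geometric change at voxel resolution — not that
segmentation survives clinical artifact levels, which requires clinical
data.

## Numerical and design choices

* **Connectivity 26** (diagonal-inclusive) everywhere by default: thin
  oblique stent wire fragments under 6-connectivity. Configurable.
* **Threshold band inclusive** at both ends (open/closed is unstated
  clinically; at CT noise levels it is immaterial).
* **Region selection** keeps every component ≥ 10% of the largest, so
  disjoint-ring stents survive speckle removal; a single connected clinical
  stent is unaffected. `fraction` is exposed.
* **Ring volume threshold** 50 voxels at 1 mm spacing: far below any support
  ring (thousands of voxels), far above speckle. Exposed.
* **Centerline**: interpolating (not smoothing) natural cubic spline —
  end-condition choice is open, natural is the least-assumption default;
  chord-length parameterization avoids ringing with uneven ring spacing.
  Two rings degrade to a straight segment gracefully.
* **Proximal direction**: an explicit hint point (default far +z, the
  superior direction in RAS-oriented NIfTI) orients the principal axis of
  the ring centroids; ring 1 is most proximal.
* **Centerline control points**: voxel-mass centroids, not peak-based
  midpoints (both are exposed). The centroid uses all ring voxels and is
  available before peaks exist, breaking a circular dependency.
* **Dice of two empty masks** is defined as 1 (loss 0).
* **Empty-mask voxelization** (wire thinner than half a voxel) is an
  explicit error, never a silent empty output.
* **File formats**: NIfTI-1 for volumes (axis-aligned affines only; oblique
  scans must be resampled upstream), CSV/JSON for point sets (coordinates at
  17 significant digits, so round trips are exact), JSON for manifests,
  configs and reports. JSON replaces YAML throughout because the deployment
  environment provides a JSON parser but no YAML parser; schemas are
  unchanged. Reports contain no timestamps, so reruns are byte-identical;
  every artifact embeds the run-config hash.

## Known limitations

* Single-device assumption: overlapping/telescoped stents are not separated.
* Pure-translation registration; rotational drift of the patient between
  scans leaks into slip vectors (deliberately, matching the clinical
  protocol; non-rigid registration is future work).
* Deep-learning segmentation is intentionally out of scope; the package
  accepts externally produced masks through the same NIfTI interface.
* Peak matching by angular rank fails above half the inter-peak angle
  (> 36° twist for five-apex rings) — far beyond physiological deformation.
* The phantom's Gaussian-noise CT is optimistic about clinical artifact
  levels (beam hardening, motion, metal bloom are absent).
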