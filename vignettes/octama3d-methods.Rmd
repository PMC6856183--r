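---
title: "Volumetric grading of retinal microaneurysms in OCTA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric grading of retinal microaneurysms in OCTA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microaneurysms (MAs) are focal capillary dilations and the earliest visible
lesion of diabetic retinopathy. OCT angiography (OCTA) records a full 3D
flow volume, but MAs are conventionally read on 2D *en face* slab
projections, which conflate depth, hide vessel connectivity, and can count
the same lesion twice when it spans two slabs. Grading MAs directly in the
volume — how many vessels feed each lesion, from which capillary plexus,
which retinal layers it occupies, its shape, its orientation relative to
the retinal pigment epithelium (RPE), and its size — requires (i) removing
volumetric projection artifacts, (ii) detecting and deduplicating lesions
across slabs, and (iii) a set of 3D grading operators. `octama3d`
implements this pipeline together with a synthetic phantom that provides
voxel-level ground truth, so every operator is validated by recovery rates
rather than by eye.

## Coordinate and geometry conventions

Volumes are 8-bit arrays indexed `(axial, x, y)`, depth increasing with the
axial index. All indices are 1-based (the native R convention); continuous
depth coordinates such as layer surfaces live on `[0, n_axial)` with voxel
`i` occupying `[i-1, i)`, so voxel centers sit at `i - 0.5`. Membership
tests against surfaces use half-open intervals. The default grid is
256 (axial) x 128 x 128 voxels: the device's 3-mm scan depth sampled with
256 voxels (11.72 µm axial pitch) and a 1.3-mm lateral crop at the 10 µm
pitch of a 3 x 3 mm / 300-A-scan acquisition. The axial sample count is not
standardized across export pipelines, so geometry is fully parameterized
and travels with raw volumes in a JSON sidecar.

## The synthetic phantom

`generate_phantom()` builds co-registered flow and structural volumes over
a layered retina with a ground-truth ledger:

* **Surfaces.** Seven boundary surfaces (ILM, GCC/INL, INL/OPL, OPL/ONL,
  outer ONL, RPE, Bruch's membrane) as smooth low-frequency perturbations of
  flat planes, with a foveal depression of the inner boundaries. Layer
  thicknesses follow typical macular anatomy (GCC 90 µm, INL 40 µm, OPL
  35 µm, ONL 70 µm).
* **Vasculature.** Superficial capillary plexus (SCP) tubes run midway
  between ILM and the GCC/INL boundary; deep vascular complex (DVC) tubes
  flank the INL at its inner and outer borders. Anatomical capillary radii
  are drawn from 3.5–6 µm (true capillary caliber, 7–12 µm diameter);
  rendered radii are floored at 7 µm, half the device's ~14 µm FWHM lateral
  resolution, which is both optically realistic and keeps sub-voxel tubes
  connected on the grid. Tubes are rasterized with an analytic
  partial-volume (soft-edge) profile rather than supersampling — the same
  anti-aliasing effect at an eighth of the memory.
* **Lesions.** Each MA draws a shape class (saccular: sphere offset
  perpendicular to its vessel axis by one radius, joined by a neck of
  0.4 x radius; fusiform: ellipsoid symmetric about the vessel axis; focal
  bulge: small lumpy sphere under the 50 µm cutoff), an orientation
  (parallel: long axis tilted <= 10° to the RPE tangent; oblique: 30–60°),
  a branch count 1–4 (a through-vessel is two branches), and a plexus
  origin. Axial placement and tilt are capped so lesions stay inside the
  retina and span at most three of the four graded layers, mirroring the
  in-vivo observation that MAs occupy one to three layers. The drawn class
  mixes default to the proportions of a graded diabetic cohort (saccular
  .596 / fusiform .154 / bulge .250; two-vessel lesions .596; DVC-only
  origin .500, and so on).
* **Cysts.** Hyporeflective ellipsoids at the INL/OPL depth. The first cyst
  is centered on the last lesion so the cyst-exclusion rule always has a
  positive case to prove itself on.
* **Projection tails.** Every flow voxel casts a tail onto deeper voxels:
  `tail(z) = β · Σ_{z'<z} F(z') · exp(−(z−z')Δ/λ) · S(z)/255`, clipped to
  255, with β = 0.15 and λ = 60 µm by default. The `S/255` factor encodes
  that projections appear on reflective tissue. Voxels whose added tail is
  at least one intensity unit and whose true flow is zero form the ledger's
  artifact mask. At the 11.7 µm axial pitch the integral gain of this model
  is ~4.7x, so tails under extended lesions remain dimmer than their
  sources; much finer axial sampling would make the same β and λ saturate
  tails to 255, which no real device shows.
* **Noise.** Additive Gaussian noise (σ = 2 intensity units) on both
  volumes, applied after tails so removal is tested under noise.

What the phantom does **not** emulate: speckle statistics, eye motion,
decorrelation physics, a connected capillary network (tubes may cross
without anastomosing; background tubes are carved away from lesions so
ground-truth branch counts stay well defined), and pathology other than
MAs and cysts. Passing recovery tests therefore demonstrates the
operators' geometric correctness, not clinical-grade performance on
patient volumes.

## Projection-artifact removal

`remove_projection()` realizes depth-sequential volumetric correction: a
corrected volume is updated in serial steps; each step partially corrects a
thin target subvolume (default thickness T = 8 voxels) using only
already-corrected voxels above it; consecutive subvolumes advance by a
stride S = 4 < T, so each voxel below the top slab is visited about T/S
times. The per-A-scan tail estimate is `α · C(z) · w(z)` with `C` the
exponentially decaying depth integral (decay 60 µm) of the current
corrected flow above `z` and `w = S(z)/255` the structural modulation;
α defaults to 0.15 and the decay to 60 µm, matching the phantom's forward
model — the natural calibration when the tail mechanism is known.

The correction itself is a keep/suppress gate in the style of
projection-resolved OCTA: voxels whose value is below `protect_factor`
(default 1.5) times the tail estimate are artifact-dominated and are
progressively driven to zero over their remaining visits; voxels above the
gate carry genuine flow and are spared. Plain subtraction
(`protect_factor = Inf`) is available but removes the tail component from
true vessels as well, which costs deep-vessel energy; the gate variant is
also exactly idempotent on the phantom (a second pass changes nothing),
because kept voxels stay above a shrinking estimate and suppressed voxels
are already zero. The gate value 1.5 spares any voxel whose genuine flow
exceeds half the local tail estimate; 2.0 was found to swallow dim lesion
tips lying beneath other vasculature. The filter is strictly per A-scan —
permuting lateral axes commutes with it — and suppression-only.

## Detection on en face slabs

The SCP slab spans ILM to GCC/INL; the DVC slab spans GCC/INL to 15 µm
below OPL/ONL, covering both plexuses that flank the INL. Projection
defaults to the **mean** over the slab: a capillary occupies ~2 of ~23 slab
voxels while lesions occupy 8+, so mean projection separates them by axial
occupancy, whereas max projection renders any capillary crossing as a
bright compact spot indistinguishable from a small MA.

Candidates are detected inside a 1-mm square ROI placed temporally and
tangentially to the foveal center (near edge on the fovea's vertical line,
vertically centered — the literal reading of tangency; the gap is
configurable). The detector mimics a grader's criteria: median background
subtraction (radius 100 µm), Otsu threshold computed within the ROI but
floored at a minimum lesion contrast of 0.18 (image scale 0–1; guards
lesion-free ROIs where Otsu would split background from capillaries),
binary opening with a 3 x 3 cross to delete capillary lines, then
connected components gated by equivalent diameter 20–200 µm and
circularity >= 0.5. Candidates over intraretinal cysts are excluded
(closed footprints: a center on the boundary is excluded), since cysts
distort the layered anatomy and can show pseudoflow. Lesions seen on both
slabs are merged once by greedy nearest-pair matching within 25 µm
(ties to the smaller id), and the merged lesion is considered visualized
on both.

## 3D grading

* **Segmentation** grows a region from the candidate seed over voxels at or
  above `max(local Otsu, 0.3 x seed intensity)`, confined to a 250 µm ball;
  a lateral-only 4-neighbour opening detaches feeding capillaries (which
  are thin in the en face plane) without clipping lesions only two voxels
  thick axially; bounded reconstruction (one lateral step, then three
  axial steps) restores the clipped rim and thin axial tips — structures a
  horizontal capillary cannot mimic.
* **Vessel branches.** The volume is binarized at half the segmentation
  threshold in a perivascular shell (150 µm beyond the mask extent), the
  mask plus a two-voxel corridor (~one capillary diameter, so
  through-vessels are properly severed even for small lesions) is removed,
  and each connected component of the *contact region* on the corridor is
  one branch. Counting contacts rather than shell components keeps a
  through-vessel at two branches even when its ends reconnect through the
  capillary mesh far from the lesion. Components below 8 voxels are
  partial-volume shards and are dropped. Each branch's plexus comes from
  the median depth of its local course (within 180 µm of the contact)
  against the GCC/INL and OPL/ONL+15 µm boundaries.
* **Origin** is SCP-only / DVC-only / both from the branch labels;
  branches below the DVC band are labeled `other` and ignored when at
  least one labeled branch exists.
* **Layer occupancy**: a layer (GCC, INL, OPL, ONL) is occupied when at
  least 5% of mask voxels (and at least 2) fall in its half-open depth
  interval at their lateral position.
* **Shape**: lesions under 50 µm are focal bulges. Otherwise the vessel
  axis is the chord of a detected through-pair (contacts on opposite sides
  of the lesion with antiparallel proximal courses) or the proximal course
  of the largest branch; the asymmetry index is the perpendicular distance
  of the mask centroid from that axis divided by the volume-equivalent
  sphere radius — fusiform at or below 0.3, saccular above. The proximal
  course (within 35 µm of the contact) matters because attached vessels
  bend back into their plexus a short distance from the lesion.
* **Orientation**: principal eigenvector of the voxel second-moment matrix
  in physical units, against an RPE tangent plane fitted by least squares
  over the mask footprint dilated 50 µm; parallel at or below 15° tilt.
  Near-isotropic lesions (axis ratio < 1.2) are degenerate and graded
  parallel with a flag.
* **Size**: exact maximum Feret diameter over voxel centers (restricted to
  surface voxels for large masks, which preserves the maximum).

The thresholds (0.3 asymmetry, 15° tilt, 50 µm bulge cutoff, 5% occupancy,
25 µm dedup tolerance) all live in one `grading_config()` record and are
covered by ledger-recovery tests, so alternative values can be re-validated
in one run.

## Statistics

`build_table()` aggregates records into the cohort table (vessel-count
histogram, origin, multi-membership layer counts, shape, orientation, mean
vessels and median size); percentages are `round(100k/n, 1)` with R's
round-half-even. Two published-style proportions (20/52 and 6/52) are not
representable under any single rounding rule that also reproduces the
remaining eighteen — `build_table` reports the half-even values (38.5,
11.5) rather than forcing both conventions. `spearman_corr()` uses
mid-ranks and the two-sided t approximation
(`t = ρ sqrt((n−2)/(1−ρ²))`), with an exact permutation p-value available
for n <= 10; `cohens_kappa()` uses marginal expected agreement, returns
exactly 1 for perfect agreement, and defines the all-constant degenerate
case as 1 with a flag. Both are cross-checked in the test suite against
independent reference implementations.

## Validation design and problem sizes

The test suite validates each operator against constructed scenes with
closed-form answers (single-column tail oracles, digitized ellipsoids at
known tilts, hand-computed rank correlations) and the whole pipeline
against phantom ground truth. The recovery cohort is ten phantoms of ten
lesions each (seeds 1–10) on the default 256 x 128 x 128 grid — large
enough for stable rates, small enough that the full suite runs in a few
minutes on one CPU. `recovery_summary()` compares graded records with the
ledger per axis; orientation is compared only for non-degenerate,
non-bulge lesions (a 20–40 µm irregular bump has no meaningful long axis,
and at 11.7 µm axial pitch its drawn obliqueness is not representable on
the grid).

## Known limitations

* The removal gate makes a per-voxel keep/suppress decision; a voxel whose
  genuine flow is far below the local tail estimate is lost. This is the
  same trade-off published projection-resolved algorithms make.
* Tails saturating at 255 (very strong β, long λ, or very fine axial
  sampling) are pointwise indistinguishable from flow; the defaults avoid
  this regime.
* The detector is a stand-in for a human grader, tuned on the phantom's
  contrast relations; on patient volumes its contrast floor and gates
  would need re-estimation.
* Branch counting assumes feeding vessels are thinner than lesions; a
  lesion at true capillary caliber (< ~25 µm) cannot be severed from its
  vessel reliably.
* `spearman_corr`'s t approximation is what small-cohort clinical reports
  conventionally use, but it is approximate at small n; use
  `exact = TRUE` below n = 10.

## Running the pipeline

```{r pipeline}
library(octama3d)
res <- run_all(pipeline_config(phantom = phantom_config(rng_seed = 1)))
res$table
res$recovery
```

Per-stage functions (`generate_phantom`, `remove_projection`,
`detect_both_slabs`, `grade_ma`, `build_table`, `write_report`) expose the
same computation piecewise, and `inst/cli/octama3d.R` wraps them for shell
use.
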