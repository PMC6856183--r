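# octama3d

Volumetric analysis of retinal microaneurysms (MAs) in OCT angiography
(OCTA), for researchers in retinal image analysis who want reproducible 3D
lesion grading instead of manual reading of 2D *en face* projections.

MAs — focal capillary dilations, the earliest lesion of diabetic
retinopathy — live in a 3D flow volume, but are conventionally graded on 2D
slab projections that conflate depth and double-count lesions spanning two
slabs. `octama3d` provides the full volumetric pipeline:

1. **Synthetic phantom with ground truth** — layered retina, superficial
   capillary plexus (SCP) and deep vascular complex (DVC), lesions of three
   shape classes (saccular / fusiform / focal bulge) attached to 1–4 vessel
   branches, intraretinal cysts, projection tails and noise, with a ledger
   recording every graded quantity per lesion.
2. **Volumetric projection-artifact removal** — depth-sequential correction
   of thin overlapping target subvolumes: the tail expected at voxel *z* of
   an A-scan is estimated as `α · C(z) · S(z)/255`, where
   `C(z) = Σ_{z'<z} F(z') e^{−(z−z')Δ/λ}` is the decaying depth integral of
   already-corrected flow above *z*; artifact-dominated voxels (below
   1.5× the estimate) are suppressed, genuine flow is spared.
3. **Detection** — SCP/DVC en face slabs, a 1-mm ROI temporal and tangential
   to the fovea, blob detection with cyst exclusion, and cross-slab
   deduplication (lesions seen on both slabs counted once).
4. **3D grading** — per lesion: number of connected vessel branches (a
   through-vessel counts as entry + exit), plexus origin (SCP/DVC/both),
   retinal layer occupancy (GCC/INL/OPL/ONL, 5% rule), shape class via the
   asymmetry index *a* = (centroid offset from the vessel axis) /
   (volume-equivalent radius), orientation to the RPE tangent plane
   (parallel ≤ 15°), and maximum Feret size.
5. **Cohort statistics** — the grading table with half-even rounded
   percentages, Spearman rank correlation (mid-ranks, t approximation),
   and Cohen's kappa.

## Worked example

```r
library(octama3d)
res <- run_all(pipeline_config(phantom = phantom_config(rng_seed = 1)))
res$table
```

```
grading_table: 7 MAs
  vessels      1              0 (0.0%)
  vessels      2              6 (85.7%)
  vessels      3              0 (0.0%)
  vessels      4              1 (14.3%)
  vessels      5+             0 (0.0%)
  origin       SCP_only       4 (57.1%)
  origin       DVC_only       2 (28.6%)
  origin       both           1 (14.3%)
  layer        GCC            7 (100.0%)
  layer        INL            5 (71.4%)
  layer        OPL            4 (57.1%)
  layer        ONL            0 (0.0%)
  shape        saccular       6 (85.7%)
  shape        fusiform       1 (14.3%)
  shape        focal_bulge    0 (0.0%)
  orientation  parallel       7 (100.0%)
  orientation  oblique        0 (0.0%)
  mean vessels 2.3, median size 115.3 um
```

The seed-1 phantom contains ten lesions; seven clear the detector's
contrast and cyst-exclusion gates and are graded. Most attach to two vessel
branches (a vessel passing through a lesion contributes an entry and an
exit), saccular shapes dominate, and every lesion occupies one to three
retinal layers — the patterns the phantom's generative mixes encode. The
removal stage scores suppression 0.933 over pure-artifact voxels with deep
vessel energy fully preserved (`res$metrics`), and `res$recovery` compares
every graded axis with the phantom ledger (7/7 lesions matched; vessel
counts, layer sets and sizes all agreeing on this seed).

Per-stage functions (`generate_phantom()`, `remove_projection()`,
`detect_both_slabs()`, `grade_ma()`, `build_table()`) expose the same
computation piecewise; `inst/cli/octama3d.R` wraps them as shell
subcommands (`simulate`, `clean`, `detect`, `characterize`, `report`,
`run-all`). The methods vignette
(`vignettes/octama3d-methods.Rmd`) documents the models, parameter choices
and limitations.

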