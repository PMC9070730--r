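# brainplane

Semi-manual registration and cell mapping of intact-brain coronal image
stacks to a reference atlas, in R.

Whole-brain activity mapping (e.g. Fos immunolabeling in cleared mouse
brains imaged by light-sheet microscopy) produces stacks of thousands of
coronal planes that must be registered to a reference atlas before
detected cells can be assigned to brain regions. Fully automated
voxel-based registration is heavy, hard to audit, and fails on damaged
or partial brains. `brainplane` implements the semi-manual alternative:
a human (or a programmatic oracle) makes a small number of easy visual
decisions, and the package turns them into a full anterior–posterior
(AP) alignment, per-plate nonrigid registration, and hierarchical
region-count tables. It is aimed at labs analyzing cleared-brain LSFM
datasets who want auditable registration with modest hardware, and at
anyone needing the 2.5D segmentation-cleanup and atlas-bookkeeping
machinery on its own.

## What it computes

- **AP alignment.** The stack's first and last planes are manually
  assigned AP coordinates (mm from bregma). Internal reference plates —
  by default the seven standard coronal plates at AP = +1.91, +1.10,
  −0.42, −0.93, −1.94, −2.95, −3.96 mm — are matched to image planes by
  a coarse-to-fine **choice game**: three candidate planes spaced by the
  current step of the schedule (200, 100, 30, 10 planes by default) are
  shown; picking a side recenters the search, picking the middle refines
  the step. Every matched plane becomes an anchor (zᵢ, APᵢ), and all
  other planes get APs by piecewise-linear interpolation
  AP(z) = APᵢ + (z − zᵢ)·(APᵢ₊₁ − APᵢ)/(zᵢ₊₁ − zᵢ). A **midpoint
  check** verifies each interval's midpoint and re-plays the game where
  it fails. The **morph ratio** per interval,
  rᵢ = (Δzᵢ/|ΔAPᵢ|)/(Z_tot/|AP_tot|), quantifies nonuniform tissue
  deformation along the AP axis (|ΔAP|-weighted mean ≡ 1).
- **Plate registration.** For each atlas plate, correspondence points
  are seeded by sampling the tissue contour (Otsu threshold on log
  intensity, largest component) and the plate outline at equal arc
  length, then hand-corrected if desired; an interpolating thin-plate
  spline f(p) = a₀ + A·p + Σᵢ wᵢ U(‖p − sᵢ‖), U(r) = r² log r², is
  fitted in both directions (image↔atlas).
- **2.5D segmentation and cleanup.** Per-plane difference-of-Gaussians
  blob segmentation, then consolidation of per-plane detections into 3D
  cells: detections within user thresholds in xy and z are linked, each
  connected component keeps its maximum-intensity member and its
  duplicate counts are erased.
- **Mapping and counting.** Each cell gets its AP from the alignment,
  is pushed through the forward warp of the nearest registered plate,
  assigned the atlas region under its landing pixel, and tabulated with
  hierarchical roll-up (each region's rolled count = direct + all
  descendants), percentages, ROI extraction and a d3-style sunburst
  JSON export.
- **Phantom generator.** A first-class synthetic-data module renders
  stacks with a known nonlinear z↔AP morph, a miniature nested-region
  atlas, cells as 3D Gaussian blobs spanning several planes (the
  duplicate mechanism), and background noise — so the whole pipeline is
  testable against ground truth without any external data.

## Worked example

Generate a phantom dataset and run the full pipeline with the
truth-backed oracle standing in for the human:

```r
library(brainplane)

# synthetic 300-plane stack + miniature atlas + ground truth
ph <- makePhantom(phantomSpec(seed = 3), dir = "demo/images")
saveAtlas(ph$atlas, "demo/atlas")
spec <- ph$truth$spec

cfg <- pipelineConfig("demo/images", "demo/out",
                      zStepUm = spec@zStepUm, pixelSizeUm = spec@pixelSizeUm,
                      referenceAps = seq(spec@apStartMm, spec@apEndMm,
                                         length.out = 9)[2:8],
                      atlasDir = "demo/atlas",
                      endpointAps = c(spec@apStartMm, spec@apEndMm))
paths <- runPipeline(cfg, chooser = oracleChooser(ph$truth, 0.025),
                     verbose = TRUE)
#> [align] 9 anchors
#> [register] 5 plates registered
#> [segment] 138 detections
#> [clean] 138 detections -> 25 cells
#> [warp] 25 cells mapped (0 unmapped)
#> [count] root rolled count 25

loadCheckpoint("tables", paths)
#>     acronym                     name direct_count rolled_count percent
#>          BR                    brain            0           25     100
#>         CTX              cortex band            0           13      52
#>         SUB           subcortex band            0           12      48
#>          HY       hypothalamic patch            7            7      28
#>          IL        infralimbic patch            7            7      28
#>          PL          prelimbic patch            6            6      24
#>          TH           thalamic patch            5            5      20
#>  unassigned outside atlas / unmapped            0            0       0
```

The 25 planted cells produced 138 raw detections (each cell is imaged
on ~5 adjacent planes at the 2.5 µm z-step); cleanup collapses them back
to exactly 25 cells, every one assigned to its true region, and the
count table rolls leaf counts (PL + IL = 13) up to their parents (CTX).
`morphProfile(loadCheckpoint("alignment", paths))` shows the recovered
nonuniform deformation (ratios < 1 where the atlas is covered by few
planes, > 1 where it is stretched), and
`linearPredictionError(...)` reports how far each plane's true AP sits
from the naive straight-line prediction — tens to hundreds of µm on
nonlinearly morphed tissue.

Interactive use on real data is the same, with
`chooser = consoleChooser(manifest, figuresDir)` (console prompts plus
side-by-side preview images) in place of the oracle, or via the CLI
wrapper `inst/scripts/brainplane.R` (`init`, `phantom`, `align`, …,
`rois`).

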