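# tibmorph

Automated micro-CT morphometry of the murine proximal tibial epiphysis,
for bone researchers studying surgically induced osteoarthritis (e.g. the
destabilisation-of-the-medial-meniscus model) who need reproducible,
operator-independent measurements of subchondral bone remodelling and
osteophyte growth from paired (operated / contralateral) scans.

## What it computes

* **Rigid surface registration** of paired bones: isosurface meshes from
  binarized stacks, iterative-closest-point alignment (closed-form
  least-squares rigid fit per iteration, correspondences from each target
  vertex to the closest location on the source surface), and voxelization
  of registered meshes back to image stacks at scan resolution.
* **Plate / trabecular compartment partition**: within two fixed windows
  (500 µm wide × 350 µm deep × 750 µm antero-posteriorly, one per plateau
  aspect) each coronal row is scanned from the proximal plate surface
  downward; the first row whose bone volume fraction BV/TV drops below
  90 % (macro-porosity ≥ 10 %) marks the plate/trabecular boundary. Per
  compartment: plate volume, plate thickness Pl.Th (mean local thickness
  of the segmented plate), trabecular TV, BV, BV/TV (%), and BMD in
  g/cm³ from a two-point hydroxyapatite calibration (0.25 / 0.75 g/cm³).
* **Local thickness** (largest inscribed sphere, distance-ridge
  construction), top-surface heat maps, and medial–lateral profiles over
  a 750 µm band.
* **Osteophyte volumetry** two ways: registered shape subtraction
  (operated − control after identical closing/dilation and cavity
  filling, restricted to a medial volume of interest) and the whole
  epiphyseal volume surrogate (Gaussian σ = 2, closing + dilation, cavity
  filling, total volume).
* **Method-validation statistics**: Pearson/Spearman r, RMS error from
  linear-regression residuals, %CV = 100·SD/mean, and Bland–Altman bias
  with 1.96 SD limits of agreement.
* **A synthetic phantom generator** — a flat-topped dome with a compact
  shell of known thickness over a honeycomb lattice of known BV/TV,
  optional medial osteophyte of known volume, two grey levels plus
  Gaussian noise — providing exact ground truth for every metric above.

## Worked example

```r
library(tibmorph)

# a 10 µm phantom pair with a 0.05 mm^3 medial osteophyte
spec <- phantom_spec(voxel_size_um = 10, plate_thickness_um = 150,
                     osteophyte_volume_mm3 = 0.05, noise_sd = 10, seed = 4)
pair <- generate_epiphysis_pair(spec)

# compartments on the healthy contralateral bone
ctrl <- binarize(pair$control, otsu_threshold(pair$control))
res <- analyse_compartments(ctrl, study_config(),
                            grey = pair$control,
                            cal = calibrate_bmd(c(0.25, 100), c(0.75, 200)))
res$medial
#> <compartment_result> (medial)
#>   plate:      volume 0.05625 mm^3, thickness 160.0 um (boundary depth 150.0 um), BMD 0.650 g/cm^3
#>   trabecular: TV 0.075 mm^3, BV 0.03825 mm^3, BV/TV 51.0%, BMD 0.650 g/cm^3

op <- binarize(pair$operated, otsu_threshold(pair$operated))
shape_difference(op, ctrl, study_config())
#> <shape_difference> osteophyte volume 0.05315 mm^3 (medial VOI, ML columns 14..97)
#>   operated-only 0.05315, control-only 9e-06, shared 1.945 mm^3
```

The medial plate reads 0.05625 mm³ and a 150 µm boundary depth — the
generated truth exactly (the 160 µm mean local thickness is the
inherent one-voxel parity of centre-to-centre distances on a 15-voxel
slab). Trabecular BV/TV 51.0 % matches the honeycomb's analytic
1−(1−0.3)² = 51 %, and both BMDs read the calibrated density of the
bone grey level (180 → 0.65 g/cm³). The shape difference recovers the
grown osteophyte to within 0.3 % of the morphology-processed truth;
nearly all of the pair overlaps (shared 1.95 mm³) and the control-only
residue is a few voxels of noise. A full study over
a manifest of specimen pairs (registration → compartments → osteophyte →
CSV) runs through `run_study()`, or from a shell via the thin CLI at
`inst/cli/tibmorph`.

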