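# granulyzer

Quantitative analysis of cytoplasmic granules in retinal pigment
epithelium (RPE) flat mounts.

RPE cells carry three families of pigmented granules — melanosomes (M),
lipofuscin (L) and the hybrid melanolipofuscin (ML) — whose counts, sizes
and 488 nm-excitation autofluorescence (AF) shift with oxidative injury
(e.g. sodium-iodate AMD models) and aging. Studies of this kind image the
flat-mounted RPE sheet as a multi-channel z-stack, draw cell boundaries by
hand, and then count, classify and localise every granule per cell.
granulyzer is that analysis as a tested, reusable R package, for
microscopists and image analysts who have a z-stack and boundary ROIs and
want the published measurement scheme without the one-off plugin.

## What it computes

Given a z-stack (AF488 + transmitted channels, optional nuclei channel)
and per-cell polygon ROIs:

* **Detection** — per-cell Otsu thresholds (bright in AF488, dark in
  transmitted light), 3-D 26-connected components, size filtering, and
  per-granule morphometry: area $A$, Crofton perimeter $P$, circularity
  $4\pi A/P^2$, ellipse aspect ratio, mean intensities, ring score.
* **Six-phenotype classification** — an auditable decision list mapping
  AF pattern and shape to L1/L2 (monolithic / irregular-aggregate
  lipofuscin), ML1/ML2 (large-round / bull's-eye melanolipofuscin),
  M1/M2 (round / spindle melanosome), with family rollups and the
  melanin:lipofuscin ratio (M + ML over L).
* **Zonal dispersion** — apical–basal zones C1–C4 (equal quarters of each
  cell's z extent); melanin concentrates in C1–C2, lipofuscin in C3.
* **AF intensity** — RGB-stack green histogram, ImageJ-style plot
  profile, and total AF summed over every in-cell voxel from apex to
  base, with a background-subtracted variant.
* **Per-cell tables** — Count, Total area, Average size (= total/count at
  printed precision), % Area, Mean intensity, nuclei counts
  (multinucleated giant cells at ≥3), granule-rich/poor labels, and cell
  morphology (regular / unusual-polygon / swollen).
* **Group statistics** — repeated-measures one-way ANOVA with Tukey HSD
  (falling back to ordinary ANOVA when subjects are not crossed with
  levels), paired two-tailed t-tests, Prism-style significance codes.
* **Synthetic scenes** — a ground-truthed generator (Voronoi cell mosaic,
  zonal granule priors, dose × day trend multipliers, nuclei, noise) so
  the full pipeline is testable without raw data.

## Worked example

```r
library(granulyzer)

scn <- simulate_scene(scene_config(n_cells = 50, seed = 7))
res <- analyze_scene(scn$stack, scn$rois, dose = "LOW_40", day = 1)

head(res$granules[, c("cell_id", "label", "family", "zone", "area_px2")])
#>    cell_id label           family zone area_px2
#> 1 cell_018    M1          MELANIN    1       10
#> 2 cell_018    M1          MELANIN    1        8
#> 3 cell_018   ML2 MELANOLIPOFUSCIN    1       41
#> 4 cell_018    M1          MELANIN    1       10
#> 5 cell_043    M2          MELANIN    1       18
#> 6 cell_023    M1          MELANIN    1       12

match_granules(res$granules, scn$truth$granules)[c("recall", "precision")]
#> $recall    [1] 0.9893162
#> $precision [1] 0.9788584
```

Each detected granule carries its phenotype (`label`), family, apical–basal
zone (1 = most apical) and cross-section area; against the generator's
ground truth this scene is recovered at ~99% recall and ~98% precision.
Per-cell summaries land in `res$cells` (e.g. `cell_001`: 24 granules,
total area 528 px², 9.4% of the cell surface, melanin:lipofuscin ratio
1.0, 1 nucleus) and are written with `write_summary_tables()`.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/rpe-granulyzer simulate --config sim.yaml --out outdir
Rscript inst/scripts/rpe-granulyzer run --stack s.tif --rois r.json --out outdir
```

## Package layout

* `R/` — implementation (imaging I/O, synthetic scenes, geometry,
  detection, classification, zonal/AF analysis, statistics, pipeline).
* `vignettes/granule-analysis-methods.Rmd` — the science: models,
  parameter defaults and their rationale, generator design, limitations.
* `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
* `inst/extdata/published_granule_summaries.csv` — transcribed published
  group-summary rows used by the table-consistency audit.
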