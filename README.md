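# cellpaintr

Segmentation-driven morphological profiling for Cell Painting microscopy, in R.

High-content screens image cells stained with five fluorescent dyes (DNA, ER,
RNA/nucleoli, actin-Golgi-plasma-membrane, mitochondria) plus brightfield, and
summarize each cell as hundreds of quantitative descriptors. The critical and
fragile step is instance segmentation: every downstream feature inherits its
errors. `cellpaintr` implements the full post-annotation workflow around a
segmentation model:

- **Ground-truth preparation** — outline annotations (border = 255 PNGs) are
  inverted, connected-component labeled (4-connectivity), cleared of
  background and debris, and dilated to restore the border pixels the outline
  stroke consumed; centered ROI cropping avoids truncated objects at image
  borders.
- **Instance segmentation from confidence maps** — given per-pixel class and
  border probability maps (from any model, or the bundled classical
  generator), instances are recovered by watershed-style flooding of the
  border map from seeds where class confidence dominates border confidence.
- **Nucleus-guided refinement** — cells containing ≥ 2 nucleus centroids are
  partitioned by nearest-centroid assignment; anucleate fragments below an
  area threshold are deleted (isolated) or merged into the neighbor with the
  weakest border evidence along the shared interface.
- **CellProfiler-compatible features** — per object and compartment (cell,
  nucleus, cytoplasm = cell − nucleus): area/shape incl. Zernike moments,
  channel correlations, granularity spectra, intensities, locations,
  neighbors, radial distributions and Haralick textures, from a
  configuration-driven catalog with a closed-form column count.
- **Evaluation and QC** — IoU-based one-to-one instance matching;
  precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)` and
  the detection-Jaccard average precision `AP = TP/(TP+FP+FN)`;
  min-max-normalized MSE/MAE comparison of feature tables per group; and
  correlation-based feature prioritization (retain one representative per
  correlated block).
- **Synthetic scenes** — a seeded generator of Cell Painting-like images with
  complete ground truth (masks, outlines, ideal confidence maps), so the
  entire pipeline is testable offline.

## Worked example

```r
library(cellpaintr)

scene <- generate_scene(scene_params(size = 256, n_cells = 8, noise = "none"),
                        seed = 7, coord = parse_image_name("BR00116991-A02-5"))
seg   <- segment_scene(scene$confidence)
cells <- refine_cells(seg$cells, seg$nuclei, scene$confidence$cell$border_map)
detection_metrics(match_instances(scene$cells, cells, iou_threshold = 0.5))
#> <detection_metrics> P=1.0000 R=1.0000 F1=1.0000 AP=1.0000 meanIoU=1.0000 (tp=8 fp=0 fn=0)

catalog  <- feature_catalog(channels = c("DNA", "ER", "RNA", "AGP", "Mito"))
features <- extract_all(catalog, scene$stack, cells, seg$nuclei)
dim(features)
#> [1]  24 447
features[1:3, c("compartment", "object_id", "AreaShape_Area",
                "Intensity_MeanIntensity_DNA", "Texture_Contrast_DNA_3")]
#>   compartment object_id AreaShape_Area Intensity_MeanIntensity_DNA Texture_Contrast_DNA_3
#> 1        cell         1           1175                    5531.117               4.902392
#> 2        cell         2           1591                    5722.948               4.402453
#> 3        cell         3           2216                    5078.852               3.392978

length(prioritize_features(features, corr_threshold = 0.9))
#> [1] 93
```

All 8 planted cells are recovered exactly (AP = 1 at IoU ≥ 0.5, mean matched
IoU 1.0); the 8 cells × 3 compartments yield 24 rows of 442 features (+ 5 key
columns), of which 93 survive redundancy reduction at |r| < 0.9.

A thin command-line wrapper ships in `exec/cellpaint` with subcommands
`synth`, `prep-masks`, `segment`, `refine`, `features`, `evaluate`, `qc`,
`prioritize` and `pipeline`; `run_pipeline()` is the programmatic equivalent
and writes masks, the feature CSV, a metrics JSON, the prioritized feature
list and the effective YAML config per run.

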