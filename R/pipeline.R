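# End-to-end pipeline orchestration: prep -> segment -> refine -> features
# (-> evaluate / qc / prioritize when references are available), with a
# validated configuration and structured on-disk outputs.

.default_config <- list(
  channels = c("DNA", "ER", "RNA", "AGP", "Mito"),
  compartments = c("cell", "nucleus", "cytoplasm"),
  class_threshold = 0.5,
  seed_margin = 0.3,
  smoothing_sigma = 2,
  cell_mode = "instance",
  min_area = NULL,
  min_area_fraction = 0.4,
  roi_size = NULL,
  zernike_degree = 9L,
  granularity_scales = 16L,
  radial_bins = 4L,
  texture_levels = 8L,
  texture_offsets = 3L,
  neighbor_distance = 5L,
  iou_threshold = 0.5,
  corr_threshold = 0.9,
  use_truth_confidence = TRUE,
  output_dir = "cellpaintr-out",
  seed = 1L)

#' Build and validate a pipeline configuration
#'
#' Defaults cover every stage parameter; unknown keys are rejected before
#' any I/O. The effective configuration is echoed as YAML into the output
#' directory on every run.
#'
#' @param ... Overrides of the defaults, or a single named list.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(.default_config))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- .default_config
  cfg[names(over)] <- over
  if (!cfg$cell_mode %in% c("instance", "semantic"))
    stop("cell_mode must be 'instance' or 'semantic'")
  if (cfg$class_threshold <= 0 || cfg$class_threshold >= 1)
    stop("class_threshold must lie strictly between 0 and 1")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file of configuration overrides.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

scene_input_paths <- function(dir, image) {
  sd <- file.path(dir, image)
  list(dir = sd,
       channels = function(chs) stats::setNames(
         file.path(sd, paste0(chs, ".tiff")), chs),
       truth_cells = file.path(sd, "truth_cells.tiff"),
       truth_nuclei = file.path(sd, "truth_nuclei.tiff"),
       conf = function(cls, kind)
         file.path(sd, sprintf("confidence_%s_%s.tiff", cls, kind)))
}

#' Run the full analysis pipeline over a dataset directory
#'
#' Consumes a dataset directory as produced by [write_scene()] (one
#' subdirectory per image with per-channel TIFFs and optional truth masks
#' and confidence maps) plus a manifest, and executes segmentation,
#' nucleus-guided refinement and feature extraction for every image;
#' when ground-truth masks are present, detection metrics are evaluated and
#' written. Outputs land in `config$output_dir`: refined masks
#' (`masks/`), the pooled feature CSV, a metrics JSON, the prioritized
#' feature list, a run log and the effective configuration. Deterministic
#' given config and seed. On-disk confidence maps are used when present
#' (and `use_truth_confidence` is `TRUE`); otherwise the classical baseline
#' generator runs on the image stack.
#'
#' @param config A [pipeline_config()].
#' @param input_dir Dataset directory.
#' @param manifest Optional manifest data frame with an `image` column;
#'   defaults to every scene subdirectory present.
#' @return List with `features` (feature table), `evaluation` (or NULL),
#'   `prioritized`, `masks` and the output directory, invisibly usable.
#' @export
run_pipeline <- function(config, input_dir, manifest = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  if (is.null(manifest)) {
    images <- sort(list.dirs(input_dir, recursive = FALSE, full.names = FALSE))
  } else {
    images <- manifest$image
  }
  if (!length(images)) stop("no input images found in ", input_dir)
  out_dir <- config$output_dir
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_effective.yaml"))
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  catalog <- feature_catalog(
    channels = config$channels, compartments = config$compartments,
    zernike_degree = config$zernike_degree,
    granularity_scales = config$granularity_scales,
    radial_bins = config$radial_bins,
    texture_levels = config$texture_levels,
    texture_offsets = config$texture_offsets,
    neighbor_distance = config$neighbor_distance)
  tables <- list(); matches_c <- list(); matches_n <- list()
  piou_c <- c(); piou_n <- c()
  for (image in images) {
    paths <- scene_input_paths(input_dir, image)
    coord <- tryCatch(parse_image_name(image), error = function(e) NULL)
    res <- tryCatch({
      stack <- read_channel_stack(paths$channels(config$channels),
                                  coord = coord)
      if (!is.null(config$roi_size))
        stack <- crop_center_roi(stack, config$roi_size)
      cls_f <- paths$conf("cell", "class")
      maps <- if (config$use_truth_confidence && file.exists(cls_f)) {
        confidence_maps(
          cell = confidence_pair(read_confidence_map(cls_f),
                                 read_confidence_map(paths$conf("cell", "border"))),
          nucleus = confidence_pair(
            read_confidence_map(paths$conf("nucleus", "class")),
            read_confidence_map(paths$conf("nucleus", "border"))))
      } else baseline_confidence_maps(stack, config$smoothing_sigma)
      if (!is.null(config$roi_size)) {
        crop_pair_maps <- function(p) confidence_pair(
          crop_center_roi(p$class_map, config$roi_size),
          crop_center_roi(p$border_map, config$roi_size))
        maps <- confidence_maps(cell = crop_pair_maps(maps$cell),
                                nucleus = crop_pair_maps(maps$nucleus))
      }
      seg <- segment_scene(maps, config$class_threshold, config$seed_margin,
                           config$cell_mode)
      cells <- refine_cells(seg$cells, seg$nuclei, maps$cell$border_map,
                            min_area = config$min_area,
                            min_area_fraction = config$min_area_fraction)
      write_mask(cells, file.path(out_dir, "masks",
                                  paste0(image, "_cells.tiff")))
      write_mask(seg$nuclei, file.path(out_dir, "masks",
                                       paste0(image, "_nuclei.tiff")))
      tab <- extract_all(catalog, stack, cells, seg$nuclei, coord = coord)
      if (file.exists(paths$truth_cells)) {
        tc <- read_mask(paths$truth_cells)
        tn <- read_mask(paths$truth_nuclei)
        if (!is.null(config$roi_size)) {
          tc <- crop_center_roi(tc, config$roi_size)
          tn <- crop_center_roi(tn, config$roi_size)
        }
        matches_c[[image]] <- match_instances(tc, cells,
                                              config$iou_threshold)
        matches_n[[image]] <- match_instances(tn, seg$nuclei,
                                              config$iou_threshold)
        piou_c[image] <- pixel_iou(tc, cells)
        piou_n[image] <- pixel_iou(tn, seg$nuclei)
      }
      logf("image=%s cells=%d nuclei=%d rows=%d", image,
           length(label_ids(cells)), length(label_ids(seg$nuclei)), nrow(tab))
      tab
    }, error = function(e) {
      stop("pipeline stage failed for image ", image, ": ",
           conditionMessage(e), call. = FALSE)
    })
    tables[[image]] <- res
  }
  features <- do.call(rbind, tables)
  rownames(features) <- NULL
  class(features) <- c("feature_table", "data.frame")
  write_feature_table(features, file.path(out_dir, "features.csv"))
  evaluation <- NULL
  if (length(matches_c)) {
    evaluation <- list(cell = evaluation_report(matches_c, piou_c),
                       nucleus = evaluation_report(matches_n, piou_n))
    jsonlite::write_json(evaluation, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  prioritized <- if (nrow(features) >= 2L)
    prioritize_features(features, config$corr_threshold) else character(0)
  writeLines(prioritized, file.path(out_dir, "prioritized_features.txt"))
  list(features = features, evaluation = evaluation,
       prioritized = prioritized, output_dir = out_dir)
}
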