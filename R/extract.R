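# Catalog-driven extraction of all feature groups per object and compartment.

#' Extract all catalog features for a segmented scene
#'
#' One row is produced per (cell object, compartment) over the catalog's
#' compartments, with columns exactly the catalog's descriptors in order.
#' The nucleus compartment of a cell is its owned nucleus (centroid inside
#' the cell) restricted to the cell; the cytoplasm is the cell minus that
#' nucleus. Objects whose compartment is empty (e.g. an anucleate cell's
#' nucleus row) receive the defined degenerate value 0 in every column, not
#' missing cells. Extraction is deterministic: the same inputs produce
#' bitwise-identical tables.
#'
#' @param catalog A [feature_catalog()].
#' @param stack A [channel_stack()] containing at least the catalog's
#'   channels.
#' @param cells,nuclei Refined integer label masks (each cell owns at most
#'   one nucleus centroid).
#' @param coord Optional [plate_coord()] used for the key columns.
#' @return A [feature_table()].
#' @export
extract_all <- function(catalog, stack, cells, nuclei, coord = NULL) {
  stopifnot(inherits(catalog, "feature_catalog"))
  missing_ch <- setdiff(catalog$channels, stack$channel_names)
  if (length(missing_ch))
    stop("catalog references channel(s) absent from the stack: ",
         paste(missing_ch, collapse = ", "))
  cells <- as_label_matrix(cells); nuclei <- as_label_matrix(nuclei)
  check_same_dim(cells, nuclei, "cells and nuclei")
  cols <- catalog_columns(catalog)
  if (is.null(coord)) coord <- stack$coord
  key_of <- function(comp, id) data.frame(
    plate = if (is.null(coord)) "NA" else coord$plate_id,
    well = if (is.null(coord)) "NA" else
      sprintf("%s%02d", coord$well_row, coord$well_col),
    site = if (is.null(coord)) 1L else coord$site,
    compartment = comp, object_id = id, stringsAsFactors = FALSE)

  comp_masks <- list()
  for (comp in catalog$compartments)
    comp_masks[[comp]] <- switch(comp,
      cell = cells,
      nucleus = nuclei_by_cell(cells, nuclei),
      cytoplasm = derive_cytoplasm(cells, nuclei))

  ids <- label_ids(cells)
  keys <- NULL; rows <- NULL
  channels <- stats::setNames(
    lapply(catalog$channels, function(ch) get_channel(stack, ch)),
    catalog$channels)
  for (comp in catalog$compartments) {
    mask <- comp_masks[[comp]]
    nbf <- if ("Neighbors" %in% catalog$groups)
      neighbor_features(mask, catalog$neighbor_distance) else NULL
    for (id in ids) {
      keys <- rbind(keys, key_of(comp, id))
      idx <- which(mask == id)
      if (!length(idx)) {
        rows <- rbind(rows, stats::setNames(numeric(length(cols)), cols))
        next
      }
      rows <- rbind(rows, object_feature_row(catalog, channels, mask, id,
                                             nbf, cols))
    }
  }
  if (is.null(keys)) {
    keys <- data.frame(plate = character(0), well = character(0),
                       site = integer(0), compartment = character(0),
                       object_id = integer(0), stringsAsFactors = FALSE)
    rows <- matrix(numeric(0), 0, length(cols), dimnames = list(NULL, cols))
  }
  tab <- feature_table(keys, as.data.frame(rows))
  rownames(tab) <- NULL
  tab
}

# single (object, compartment) feature row, computed on a padded crop
object_feature_row <- function(catalog, channels, mask, id, nbf, cols) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask == id)
  pad <- max(catalog$granularity_scales + 1L, max(catalog$texture_offsets),
             2L)
  bb <- pad_bbox(bbox_of(idx, H), pad, H, W)
  bin <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE] == id
  offset <- c(bb[1] - 1L, bb[3] - 1L)
  chans <- lapply(channels, function(ch)
    ch[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE])
  out <- numeric(0)
  g <- catalog$groups
  if ("AreaShape" %in% g) {
    as_ <- areashape_features(bin, offset)
    names(as_) <- paste0("AreaShape_", names(as_))
    zm <- zernike_magnitudes(bin, catalog$zernike_degree)
    names(zm) <- paste0("AreaShape_", names(zm))
    out <- c(out, as_, zm)
  }
  if ("Correlation" %in% g) {
    cp <- channel_pairs(catalog$channels)
    for (i in seq_len(nrow(cp))) {
      cf <- if (sum(bin) >= 2L)
        correlation_features(chans[[cp[i, 1]]], chans[[cp[i, 2]]], bin)
      else stats::setNames(numeric(8), .correlation_names)
      names(cf) <- sprintf("Correlation_%s_%s_%s", names(cf),
                           cp[i, 1], cp[i, 2])
      out <- c(out, cf)
    }
  }
  if ("Granularity" %in% g)
    for (nm in catalog$channels) {
      gs <- granularity_spectrum(chans[[nm]], bin, catalog$granularity_scales)
      names(gs) <- sprintf("Granularity_%d_%s", seq_along(gs), nm)
      out <- c(out, gs)
    }
  if ("Intensity" %in% g)
    for (nm in catalog$channels) {
      iv <- intensity_features(chans[[nm]], bin)
      names(iv) <- sprintf("Intensity_%s_%s", names(iv), nm)
      out <- c(out, iv)
    }
  if ("Location" %in% g)
    out <- c(out, location_features(chans, bin, offset))
  if ("Neighbors" %in% g) {
    row <- nbf[nbf$object_id == id, , drop = FALSE]
    nv <- if (nrow(row)) unlist(row[1, -1]) else numeric(5)
    names(nv) <- sprintf("Neighbors_%s_%d", .neighbor_names,
                         catalog$neighbor_distance)
    out <- c(out, nv)
  }
  if ("RadialDistribution" %in% g)
    for (nm in catalog$channels) {
      rd <- radial_distribution(chans[[nm]], bin, catalog$radial_bins)
      # "FracAtD_1of4" -> "RadialDistribution_FracAtD_<channel>_1of4"
      names(rd) <- sprintf("RadialDistribution_%s_%s_%s",
                           sub("_.*$", "", names(rd)), nm,
                           sub("^[^_]+_", "", names(rd)))
      out <- c(out, rd)
    }
  if ("Texture" %in% g)
    for (nm in catalog$channels)
      for (off in catalog$texture_offsets) {
        hv <- haralick_texture(chans[[nm]], bin, catalog$texture_levels, off)
        names(hv) <- sprintf("Texture_%s_%s_%d", names(hv), nm, off)
        out <- c(out, hv)
      }
  out[cols]
}
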