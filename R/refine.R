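# Nucleus-guided refinement of cell instance masks: splitting multi-nucleated
# detections, merging/removing anucleate fragments, and compartment
# derivation.

# rounded (0-based) centroid pixels of each nucleus; rows named by label.
# Round-half-up for determinism, clipped into the image.
nucleus_centroid_pixels <- function(nuclei) {
  cen <- label_centroids(nuclei)
  if (!nrow(cen)) return(cen)
  out <- cbind(row = pmin(pmax(floor(cen[, 1] + 0.5), 0), nrow(nuclei) - 1L),
               col = pmin(pmax(floor(cen[, 2] + 0.5), 0), ncol(nuclei) - 1L))
  rownames(out) <- rownames(cen)
  out
}

# cell label under each nucleus centroid pixel; named by nucleus label
centroid_owners <- function(cells, nuclei) {
  cen <- nucleus_centroid_pixels(nuclei)
  if (!nrow(cen)) return(integer(0))
  stats::setNames(cells[cbind(cen[, 1] + 1L, cen[, 2] + 1L)],
                  rownames(cen))
}

#' Split cell instances containing multiple nucleus centroids
#'
#' A nucleus belongs to a cell iff its rounded centroid pixel lies inside that
#' cell. Every cell owning two or more centroids is partitioned by assigning
#' each of its pixels to the nearest owned centroid (Euclidean distance, ties
#' to the lower nucleus label). Split parts receive fresh labels above the
#' current maximum, in ascending order of their nucleus label; cells with at
#' most one centroid are left untouched. The nucleus mask is never modified.
#'
#' @param cells,nuclei Integer label masks of equal dimensions.
#' @return Refined cell label mask.
#' @export
split_multinucleated <- function(cells, nuclei) {
  cells <- as_label_matrix(cells); nuclei <- as_label_matrix(nuclei)
  check_same_dim(cells, nuclei, "cells and nuclei")
  owners <- centroid_owners(cells, nuclei)
  owners <- owners[owners > 0L]
  if (!length(owners)) return(cells)
  multi <- as.integer(names(which(table(owners) >= 2L)))
  if (!length(multi)) return(cells)
  cen <- nucleus_centroid_pixels(nuclei)
  out <- cells
  next_label <- max(cells)
  H <- nrow(cells)
  for (cell_id in sort(multi)) {
    nuc_ids <- sort(as.integer(names(owners)[owners == cell_id]))
    pts <- cen[as.character(nuc_ids), , drop = FALSE]
    idx <- which(cells == cell_id)
    co <- idx_coords(idx, H)
    # squared distance of every cell pixel to every owned centroid
    d2 <- outer(co[, 1], pts[, 1], "-")^2 + outer(co[, 2], pts[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")  # tie -> lower nucleus label
    for (k in seq_along(nuc_ids)) {
      next_label <- next_label + 1L
      out[idx[nearest == k]] <- next_label
    }
  }
  out
}

#' Merge or remove anucleate cell fragments
#'
#' Detected cells containing no nucleus centroid and smaller than `min_area`
#' are treated as artifacts: fragments with no 8-connected neighboring cell
#' are removed as noise; fragments adjacent to other cells are merged into
#' the neighbor with the lowest mean border confidence along the shared
#' interface (low border evidence between two regions is taken as evidence
#' they are the same object; ties go to the longest shared interface, then the
#' lower label). Fragments are processed in ascending label order against the
#' evolving mask. Nucleated cells and large anucleate cells are unchanged.
#'
#' @param cells,nuclei Integer label masks of equal dimensions.
#' @param cell_border_map Border-confidence matrix of the same dimensions.
#' @param min_area Area threshold in pixels; defaults to
#'   `min_area_fraction` times the median area of nucleated cells
#'   (100 px when no nucleated cell exists).
#' @param min_area_fraction Fraction used for the default `min_area`
#'   (default 0.4).
#' @return Refined cell label mask.
#' @export
merge_or_remove_fragments <- function(cells, nuclei, cell_border_map,
                                      min_area = NULL,
                                      min_area_fraction = 0.4) {
  cells <- as_label_matrix(cells); nuclei <- as_label_matrix(nuclei)
  check_same_dim(cells, nuclei, "cells and nuclei")
  check_same_dim(cells, cell_border_map, "cells and border map")
  owners <- centroid_owners(cells, nuclei)
  nucleated <- unique(owners[owners > 0L])
  areas <- label_areas(cells)
  if (is.null(min_area)) {
    nuc_areas <- areas[as.character(nucleated)]
    min_area <- if (length(nuc_areas))
      min_area_fraction * stats::median(nuc_areas) else 100
  }
  if (min_area <= 0) stop("min_area must be positive")
  frag <- setdiff(as.integer(names(areas)[areas < min_area]), nucleated)
  if (!length(frag)) return(cells)
  out <- cells
  H <- nrow(cells); W <- ncol(cells)
  for (id in sort(frag)) {
    idx <- which(out == id)
    if (!length(idx)) next   # absorbed earlier in this pass
    co <- idx_coords(idx, H) + 1L
    # 8-neighbour labels of each fragment pixel in the evolving mask
    nb_labels <- integer(0)
    nb_border <- numeric(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- co[, 1] + dr; cc <- co[, 2] + dc
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      if (!any(ok)) next
      lab <- out[cbind(rr[ok], cc[ok])]
      sel <- lab > 0L & lab != id
      if (!any(sel)) next
      # interface evidence: border confidence at the fragment-side pixel
      nb_labels <- c(nb_labels, lab[sel])
      nb_border <- c(nb_border, cell_border_map[cbind(co[ok, 1], co[ok, 2])][sel])
    }
    if (!length(nb_labels)) {
      out[idx] <- 0L           # poorly connected: noise
      next
    }
    mean_b <- tapply(nb_border, nb_labels, mean)
    len <- tapply(nb_border, nb_labels, length)
    cand <- as.integer(names(mean_b))
    ord <- order(round(mean_b, 12), -len, cand)
    out[idx] <- cand[ord[1]]
  }
  out
}

#' Derive the cytoplasm compartment
#'
#' The cytoplasm of cell *k* is the set of its pixels not covered by its own
#' nucleus (the nucleus whose rounded centroid lies inside cell *k*); labels
#' are copied from the cell mask, so per object
#' `area(cell) = area(nucleus within cell) + area(cytoplasm)`.
#'
#' @param cells,nuclei Integer label masks of equal dimensions, refined so
#'   each cell owns at most one nucleus centroid.
#' @return Cytoplasm label mask with cell label ids.
#' @export
derive_cytoplasm <- function(cells, nuclei) {
  cells <- as_label_matrix(cells); nuclei <- as_label_matrix(nuclei)
  check_same_dim(cells, nuclei, "cells and nuclei")
  owners <- centroid_owners(cells, nuclei)
  out <- cells
  for (nuc in as.integer(names(owners))) {
    cell_id <- owners[[as.character(nuc)]]
    if (cell_id == 0L) next
    out[nuclei == nuc & cells == cell_id] <- 0L
  }
  out
}

#' Nucleus compartment mask keyed by cell id
#'
#' Relabels each owned nucleus (restricted to its cell) with the owning cell's
#' label, so the three compartment masks of one object share an id.
#'
#' @inheritParams derive_cytoplasm
#' @return Label mask of nucleus pixels carrying cell ids.
#' @export
nuclei_by_cell <- function(cells, nuclei) {
  cells <- as_label_matrix(cells); nuclei <- as_label_matrix(nuclei)
  check_same_dim(cells, nuclei, "cells and nuclei")
  owners <- centroid_owners(cells, nuclei)
  out <- matrix(0L, nrow(cells), ncol(cells))
  for (nuc in as.integer(names(owners))) {
    cell_id <- owners[[as.character(nuc)]]
    if (cell_id == 0L) next
    out[nuclei == nuc & cells == cell_id] <- cell_id
  }
  out
}

#' Full nucleus-guided refinement
#'
#' [split_multinucleated()] followed by [merge_or_remove_fragments()].
#'
#' @inheritParams merge_or_remove_fragments
#' @return Refined cell label mask.
#' @export
refine_cells <- function(cells, nuclei, cell_border_map, min_area = NULL,
                         min_area_fraction = 0.4) {
  merged <- split_multinucleated(cells, nuclei)
  merge_or_remove_fragments(merged, nuclei, cell_border_map,
                            min_area = min_area,
                            min_area_fraction = min_area_fraction)
}
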