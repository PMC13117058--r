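#' Convert outline annotations into an instance label mask
#'
#' Outline annotations mark object borders with value 255 on a 0 background.
#' Ground-truth instance masks are recovered by (1) inverting the outline so
#' interiors become foreground, (2) labeling 4-connected components,
#' (3) removing the background component(s) touching the image border and any
#' region smaller than `min_area`, and (4) renumbering the surviving instances
#' 1..N in raster order of their first pixel. Border restoration is a separate
#' step, [restore_borders()].
#'
#' 4-connectivity is used for interiors so that 8-connected outline strokes
#' seal the regions they enclose.
#'
#' @param outline Matrix with exactly the values \{0, 255\} (or \{0, 1\}).
#' @param min_area Minimum instance area in pixels; smaller interior regions
#'   are treated as annotation debris and dropped.
#' @param expected_count Optional reference object count; when supplied, a
#'   warning is raised if the result disagrees.
#' @return Integer label mask (0 = background).
#' @export
outlines_to_instances <- function(outline, min_area = 15L,
                                  expected_count = NULL) {
  outline <- as.matrix(outline)
  vals <- sort(unique(as.vector(outline)))
  if (!all(vals %in% c(0, 1)) && !all(vals %in% c(0, 255)))
    stop("outline image is not binary {0, 255}: values ",
         paste(utils::head(vals, 5), collapse = ", "))
  interior <- outline == 0
  lab <- cc_label(interior)
  drop <- border_labels(lab)
  areas <- label_areas(lab)
  drop <- union(drop, as.integer(names(areas)[areas < min_area]))
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- renumber_raster(lab)
  if (!is.null(expected_count)) {
    n <- length(label_ids(lab))
    if (n != expected_count)
      warning("instance count ", n, " differs from reference count ",
              expected_count)
  }
  lab
}

#' Dilate instances to restore border pixels
#'
#' Outline-derived masks lack the border pixels consumed by the outline
#' stroke. Each instance is dilated by a square structuring element of side
#' `2r + 1` with `r = max(1, round(0.5 + sqrt(mean_area) / 50))`, a radius
#' tuned to the mean object area (config-overridable via `radius`). Pixels
#' claimed by two or more instances go to the instance whose nearest original
#' pixel is closest (Euclidean); ties go to the lower label id. The instance
#' count never changes and no instance shrinks.
#'
#' @param mask Integer label mask.
#' @param mean_area Mean object area in pixels used to tune the dilation
#'   radius; defaults to the mean area of the mask's own instances.
#' @param radius Optional explicit radius overriding the area-based rule.
#' @return Label mask with dilated instances.
#' @export
restore_borders <- function(mask, mean_area = NULL, radius = NULL) {
  mask <- as_label_matrix(mask)
  ids <- label_ids(mask)
  if (!length(ids)) return(mask)
  if (is.null(radius)) {
    if (is.null(mean_area)) mean_area <- mean(label_areas(mask))
    radius <- max(1L, as.integer(floor(0.5 + (0.5 + sqrt(mean_area) / 50))))
  }
  r <- as.integer(radius)
  H <- nrow(mask); W <- ncol(mask)
  brush <- matrix(1, 2L * r + 1L, 2L * r + 1L)
  best <- matrix(Inf, H, W)
  out <- matrix(0L, H, W)
  for (id in ids) {
    idx <- which(mask == id)
    bb <- pad_bbox(bbox_of(idx, H), r, H, W)
    sub <- mask[bb[1]:bb[2], bb[3]:bb[4]] == id
    bin <- matrix(as.numeric(sub), nrow(sub), ncol(sub))
    claim <- EBImage::dilate(bin, brush) > 0
    # Euclidean distance from every crop pixel to the instance's original
    # pixels: distmap of the complement
    d <- EBImage::distmap(1 - bin)
    d <- matrix(d, nrow(bin), ncol(bin))
    rows <- bb[1]:bb[2]; cols <- bb[3]:bb[4]
    sel <- which(claim)
    gidx <- (rep(cols, each = length(rows))[sel] - 1L) * H +
      rep(rows, times = length(cols))[sel]
    dv <- d[sel]
    better <- dv < best[gidx] - 1e-9   # strict improvement; ties keep the
    out[gidx[better]] <- id            # earlier (lower) label
    best[gidx[better]] <- dv[better]
  }
  out
}

#' Crop the centered region of interest
#'
#' Returns the centered `size` x `size` window of an image, mask or channel
#' stack; the offset along each axis is `floor((dim - size) / 2)`. Instances
#' extending beyond the window are truncated, not removed.
#'
#' @param x Matrix, H x W x C array, or [channel_stack()].
#' @param size Window side length in pixels.
#' @return Cropped object of the same kind.
#' @export
crop_center_roi <- function(x, size) {
  if (inherits(x, "channel_stack")) {
    px <- crop_center_roi(x$pixels, size)
    return(channel_stack(px, x$channel_names, x$coord))
  }
  d <- dim(x)
  if (size > d[1] || size > d[2])
    stop("crop size ", size, " exceeds image dimensions ",
         d[1], "x", d[2])
  r0 <- (d[1] - size) %/% 2L
  c0 <- (d[2] - size) %/% 2L
  if (length(d) == 3L) {
    x[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), , drop = FALSE]
  } else {
    x[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), drop = FALSE]
  }
}

#' Draw 1-pixel outlines of a label mask
#'
#' The inverse direction of [outlines_to_instances()]: instance boundary
#' pixels (8-neighbourhood meets a different label or background) are set to
#' 255 on a 0 background, the on-disk outline convention.
#'
#' @param mask Integer label mask.
#' @return Matrix with values \{0, 255\}.
#' @export
draw_outlines <- function(mask) {
  mask <- as_label_matrix(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[label_boundaries(mask)] <- 255L
  out
}
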