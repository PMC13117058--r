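# Internal label-mask helpers. Masks are plain integer matrices indexed
# [row, col], row 1 = top; label 0 is background. Reported pixel coordinates
# are 0-based (row, column).

label_ids <- function(mask) {
  u <- sort(unique(as.integer(mask)))
  u[u > 0L]
}

# areas of each positive label, named by label
label_areas <- function(mask) {
  v <- as.integer(mask)
  v <- v[v > 0L]
  if (!length(v)) return(integer(0))
  tab <- tabulate(v)
  ids <- which(tab > 0L)
  stats::setNames(tab[ids], ids)
}

# renumber labels 1..N in raster (row-major, top-left origin) order of each
# label's first pixel
renumber_raster <- function(mask) {
  ids <- label_ids(mask)
  if (!length(ids)) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask > 0L)
  r <- (idx - 1L) %% H
  cc <- (idx - 1L) %/% H
  raster <- r * W + cc
  first <- tapply(raster, mask[idx], min)
  ord <- names(sort(first))
  lut <- integer(max(ids))
  lut[as.integer(ord)] <- seq_along(ord)
  out <- mask
  out[idx] <- lut[mask[idx]]
  out
}

# bounding box (row1, row2, col1, col2) of a set of linear indices
bbox_of <- function(idx, H) {
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  c(min(r), max(r), min(cc), max(cc))
}

# pad a bounding box by m pixels, clipped to the image
pad_bbox <- function(bb, m, H, W) {
  c(max(1L, bb[1] - m), min(H, bb[2] + m),
    max(1L, bb[3] - m), min(W, bb[4] + m))
}

# 0-based (row, col) coordinates of linear indices
idx_coords <- function(idx, H) {
  cbind(row = (idx - 1L) %% H, col = (idx - 1L) %/% H)
}

# labels touching the image border
border_labels <- function(mask) {
  u <- unique(c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)]))
  u[u > 0L]
}

# binary (0/1) matrix of pixels whose 4-neighbourhood leaves the object set;
# image border counts as outside
edge_pixels <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- bin
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  (core == 1L) & !nb
}

# pixels of a label mask whose 8-neighbourhood contains a different label or
# background (instance boundaries)
label_boundaries <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(-1L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  core <- mask
  out <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
    out <- out | (nb != core)
  }
  out & (core > 0L)
}

# centroids (0-based row, col means) per label; rows named by label id
label_centroids <- function(mask) {
  ids <- label_ids(mask)
  if (!length(ids))
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  H <- nrow(mask)
  idx <- which(mask > 0L)
  co <- idx_coords(idx, H)
  lab <- mask[idx]
  r <- tapply(co[, 1], lab, mean)
  cc <- tapply(co[, 2], lab, mean)
  out <- cbind(row = as.numeric(r), col = as.numeric(cc))
  rownames(out) <- names(r)
  out
}

# 4-connected components of a binary matrix via EBImage (verified 4-connected)
cc_label <- function(bin) {
  m <- EBImage::bwlabel(matrix(as.numeric(bin != 0), nrow(bin), ncol(bin)))
  storage.mode(m) <- "integer"
  matrix(m, nrow(bin), ncol(bin))
}

as_label_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  x
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!all(dim(a)[1:2] == dim(b)[1:2]))
    stop("dimension mismatch between ", what, ": ",
         paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"))
  invisible(TRUE)
}
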