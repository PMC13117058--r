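# Per-object neighborhood features of a label mask.

# Euclidean distance from every pixel of a padded crop to the nearest pixel
# of `target` (logical matrix)
dist_to_set <- function(target) {
  d <- EBImage::distmap(1 - target)
  matrix(d, nrow(target), ncol(target))
}

#' Neighbor features for every object of a label mask
#'
#' Per object: `NumberOfNeighbors`, the count of other objects whose nearest
#' pixel lies within `distance` pixels (Euclidean) of the object;
#' `PercentTouching`, the percentage of the object's boundary pixels lying
#' within `distance` of another object; `FirstClosestDistance` and
#' `SecondClosestDistance`, centroid-to-centroid distances to the two nearest
#' other objects (0 when absent); and `AngleBetweenNeighbors`, the angle in
#' degrees subtended at the object's centroid by its two closest neighbors
#' (0 with fewer than 2 other objects).
#'
#' @param mask Integer label mask.
#' @param distance Expansion distance in pixels (default 5).
#' @return Data frame with one row per label, ordered by label id.
#' @export
neighbor_features <- function(mask, distance = 5L) {
  mask <- as_label_matrix(mask)
  ids <- label_ids(mask)
  n <- length(ids)
  out <- data.frame(object_id = ids,
                    NumberOfNeighbors = numeric(n),
                    PercentTouching = numeric(n),
                    FirstClosestDistance = numeric(n),
                    SecondClosestDistance = numeric(n),
                    AngleBetweenNeighbors = numeric(n))
  if (!n) return(out)
  H <- nrow(mask); W <- ncol(mask)
  cen <- label_centroids(mask)
  bounds <- label_boundaries(mask)
  pad <- as.integer(ceiling(distance)) + 1L
  for (k in seq_len(n)) {
    id <- ids[k]
    idx <- which(mask == id)
    bb <- pad_bbox(bbox_of(idx, H), pad, H, W)
    sub <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    # distance from every crop pixel to this object
    d_self <- dist_to_set(sub == id)
    others <- unique(sub[sub > 0L & sub != id & d_self <= distance])
    out$NumberOfNeighbors[k] <- length(others)
    # distance from this object's boundary pixels to any other object
    if (any(sub > 0L & sub != id)) {
      d_others <- dist_to_set(sub > 0L & sub != id)
      bsub <- bounds[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE] & sub == id
      nb <- sum(bsub)
      if (nb > 0)
        out$PercentTouching[k] <- 100 * sum(d_others[bsub] <= distance) / nb
    }
    if (n >= 2L) {
      dc <- sqrt((cen[, 1] - cen[k, 1])^2 + (cen[, 2] - cen[k, 2])^2)
      dc[k] <- Inf
      ord <- order(dc, as.integer(rownames(cen)))
      out$FirstClosestDistance[k] <- dc[ord[1]]
      if (n >= 3L) {
        out$SecondClosestDistance[k] <- dc[ord[2]]
        v1 <- cen[ord[1], ] - cen[k, ]
        v2 <- cen[ord[2], ] - cen[k, ]
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        out$AngleBetweenNeighbors[k] <-
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }
    }
  }
  out
}
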