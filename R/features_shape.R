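# Area/shape descriptors of a single object. Objects are passed as logical
# matrices marking the object's pixels; coordinates are 0-based (row, col)
# within that matrix, with an optional (row, col) offset for objects handed
# in as crops of a larger scene.

# 8-connected labeling (4-connected pass + merging of diagonal adjacencies)
cc_label8 <- function(bin) {
  lab <- cc_label(bin)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    r <- seq_len(H - 1L)
    cs <- if (d[2] > 0) seq_len(W - 1L) else 2:W
    a <- lab[r, cs, drop = FALSE]
    b <- lab[r + 1L, cs + d[2], drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      for (k in which(sel)) {
        ra <- find(a[k]); rb <- find(b[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lut <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- lut[lab[lab > 0L]]
  out
}

# Moore-neighbour boundary tracing of one 8-connected component containing
# start index (r, c); returns total contour path length (axial 1, diagonal
# sqrt(2)). Isolated pixels contribute length 1.
.moore_dirs <- cbind(dr = c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
                     dc = c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L))

trace_contour_length <- function(bin, start_r, start_c) {
  H <- nrow(bin); W <- ncol(bin)
  at <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && bin[r, c]
  # backtrack starts west of the raster-first pixel (guaranteed background)
  p <- c(start_r, start_c)
  dir_back <- 8L   # index in .moore_dirs of the backtrack ((0,-1) = west)
  first_move <- NA
  total <- 0
  steps <- 0L
  max_steps <- 8L * sum(bin) + 8L
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- (dir_back + k - 1L) %% 8L + 1L  # clockwise scan from backtrack
      nr <- p[1] + .moore_dirs[d, 1]; nc <- p[2] + .moore_dirs[d, 2]
      if (at(nr, nc)) {
        step <- if (.moore_dirs[d, 1] != 0L && .moore_dirs[d, 2] != 0L)
          sqrt(2) else 1
        if (is.na(first_move[1])) first_move <- c(p, d)
        else if (p[1] == start_r && p[2] == start_c && d == first_move[3] &&
                 steps > 0L)
          return(total)              # Jacob's stopping criterion
        total <- total + step
        # new backtrack: direction from the new pixel towards the previous
        # scan position (the last background neighbour visited)
        prev_d <- (d - 2L) %% 8L + 1L
        br <- p[1] + .moore_dirs[prev_d, 1]; bc <- p[2] + .moore_dirs[prev_d, 2]
        dir_back <- which(.moore_dirs[, 1] == br - nr &
                            .moore_dirs[, 2] == bc - nc)
        p <- c(nr, nc)
        found <- TRUE
        steps <- steps + 1L
        break
      }
    }
    if (!found) return(1)            # isolated pixel
    if (steps > max_steps) return(total)
  }
}

# perimeter of an object (sum of outer contour lengths over its 8-connected
# components)
object_perimeter <- function(bin) {
  lab <- cc_label8(bin)
  total <- 0
  H <- nrow(bin)
  for (id in label_ids(lab)) {
    idx <- which(lab == id)
    co <- idx_coords(idx, H)
    ord <- order(co[, 1], co[, 2])[1]      # raster-first pixel
    total <- total + trace_contour_length(lab == id,
                                          co[ord, 1] + 1L, co[ord, 2] + 1L)
  }
  total
}

# convex hull helpers on 0-based pixel-centre coordinates
convex_hull_pts <- function(co) {
  pts <- unique(co)
  if (nrow(pts) < 3L) return(pts)
  h <- grDevices::chull(pts[, 2], pts[, 1])   # x = col, y = row
  pts[h, , drop = FALSE]
}

# number of object pixels inside (or on) the convex hull polygon
convex_area_pixels <- function(bin) {
  H <- nrow(bin)
  idx <- which(bin)
  co <- idx_coords(idx, H)
  hull <- convex_hull_pts(co)
  if (nrow(hull) < 3L) return(length(idx))     # degenerate: collinear object
  bb <- bbox_of(idx, H)
  rows <- (bb[1]:bb[2]) - 1L; cols <- (bb[3]:bb[4]) - 1L
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  inside <- rep(TRUE, length(pr))
  n <- nrow(hull)
  # chull returns vertices clockwise in (x, y); with y = row increasing down
  # this is counter-clockwise in screen coords -- test sign-consistently
  sgn <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    cr <- (hull[j, 2] - hull[i, 2]) * (pr - hull[i, 1]) -
      (hull[j, 1] - hull[i, 1]) * (pc - hull[i, 2])
    if (sgn == 0) sgn <- sign(sum(cr))
    inside <- inside & (sgn * cr >= -1e-9)
  }
  sum(inside)
}

min_feret <- function(hull) {
  n <- nrow(hull)
  if (n < 2L) return(0)
  if (n == 2L) return(0)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) { widths[i] <- Inf; next }
    # distance of all vertices from the edge line
    d <- abs((hull[, 1] - hull[i, 1]) * e[2] -
               (hull[, 2] - hull[i, 2]) * e[1]) / len
    widths[i] <- max(d)
  }
  min(widths)
}

euler_number <- function(bin) {
  lab8 <- cc_label8(bin)
  ncomp <- max(lab8)
  H <- nrow(bin); W <- ncol(bin)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- bin
  holes <- cc_label(!pad)
  hole_ids <- setdiff(label_ids(holes), border_labels(holes))
  ncomp - length(hole_ids)
}

# Euclidean distance of each object pixel to the nearest background pixel
object_radii <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- bin
  d <- EBImage::distmap(pad)
  d <- matrix(d, H + 2L, W + 2L)[2:(H + 1L), 2:(W + 1L)]
  d[bin]
}

#' Area and shape features of one object
#'
#' Returns the 25 scalar shape descriptors: Area; Perimeter (outer boundary
#' path length, axial steps 1 and diagonal steps sqrt(2)); FormFactor
#' `4 pi Area / Perimeter^2`; Eccentricity, MajorAxisLength, MinorAxisLength
#' and Orientation from second central moments (with the 1/12 pixel-variance
#' correction); Solidity (Area / ConvexArea); Extent (Area / bounding-box
#' area); EquivalentDiameter; Compactness (`2 pi E[r^2] / Area`, 1 for a
#' disk); EulerNumber (components minus holes); ConvexArea; bounding-box
#' area/width/height/min-corner; Max/Min Feret diameters (on the pixel-centre
#' convex hull); and Mean/Median/Maximum radius (Euclidean
#' distance-to-boundary); plus the 0-based centroid (CenterRow, CenterCol).
#'
#' @param bin Logical matrix marking the object's pixels.
#' @param offset 0-based (row, col) offset of `bin` within the full scene,
#'   added to location-bearing outputs.
#' @return Named numeric vector of length 25.
#' @export
areashape_features <- function(bin, offset = c(0, 0)) {
  bin <- bin != 0
  idx <- which(bin)
  if (!length(idx)) stop("empty object")
  H <- nrow(bin)
  co <- idx_coords(idx, H)
  area <- length(idx)
  per <- object_perimeter(bin)
  mu_r <- mean(co[, 1]); mu_c <- mean(co[, 2])
  urr <- mean((co[, 1] - mu_r)^2) + 1 / 12
  ucc <- mean((co[, 2] - mu_c)^2) + 1 / 12
  urc <- mean((co[, 1] - mu_r) * (co[, 2] - mu_c))
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  l1 <- (urr + ucc + common) / 2
  l2 <- (urr + ucc - common) / 2
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  orientation <- 0.5 * atan2(2 * -urc, ucc - urr) * 180 / pi
  hull <- convex_hull_pts(co)
  conv_area <- convex_area_pixels(bin)
  maxferet <- if (nrow(hull) >= 2L)
    sqrt(max(as.matrix(stats::dist(hull))^2)) else 0
  bb <- bbox_of(idx, H)
  radii <- object_radii(bin)
  r2 <- (co[, 1] - mu_r)^2 + (co[, 2] - mu_c)^2
  c(Area = area,
    Perimeter = per,
    FormFactor = if (per > 0) 4 * pi * area / per^2 else 0,
    Eccentricity = ecc,
    MajorAxisLength = 4 * sqrt(pmax(l1, 0)),
    MinorAxisLength = 4 * sqrt(pmax(l2, 0)),
    Orientation = orientation,
    Solidity = area / conv_area,
    Extent = area / ((bb[2] - bb[1] + 1) * (bb[4] - bb[3] + 1)),
    EquivalentDiameter = sqrt(4 * area / pi),
    Compactness = 2 * pi * mean(r2) / area,
    EulerNumber = euler_number(bin),
    ConvexArea = conv_area,
    BoundingBoxArea = (bb[2] - bb[1] + 1) * (bb[4] - bb[3] + 1),
    BoundingBoxWidth = bb[4] - bb[3] + 1,
    BoundingBoxHeight = bb[2] - bb[1] + 1,
    BoundingBoxMinRow = bb[1] - 1 + offset[1],
    BoundingBoxMinCol = bb[3] - 1 + offset[2],
    MaxFeretDiameter = maxferet,
    MinFeretDiameter = min_feret(hull),
    MeanRadius = mean(radii),
    MedianRadius = stats::median(radii),
    MaximumRadius = max(radii),
    CenterRow = mu_r + offset[1],
    CenterCol = mu_c + offset[2])
}

# radial Zernike polynomial R_nm evaluated at rho
zernike_radial <- function(n, m, rho) {
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

#' Zernike moment magnitudes of an object's shape
#'
#' The object is mapped onto the unit disk via its centroid and minimum
#' enclosing radius; the magnitude `|A_nm|` of each Zernike moment
#' `A_nm = (n+1)/pi * sum_p w V*_nm(p)` with uniform pixel weights
#' `w = 1/N` is returned for all orders `0 <= m <= n <= degree`, `n - m`
#' even (30 magnitudes at the default degree 9). Magnitudes are invariant
#' under rotation of the mask.
#'
#' @param bin Logical matrix marking the object's pixels.
#' @param degree Maximum order `n` (default 9).
#' @return Named numeric vector, one entry per (n, m).
#' @export
zernike_magnitudes <- function(bin, degree = 9L) {
  bin <- bin != 0
  idx <- which(bin)
  if (!length(idx)) stop("empty object")
  H <- nrow(bin)
  co <- idx_coords(idx, H)
  mu_r <- mean(co[, 1]); mu_c <- mean(co[, 2])
  dr <- co[, 1] - mu_r; dc <- co[, 2] - mu_c
  R <- sqrt(max(dr^2 + dc^2))
  if (R == 0) R <- 1
  rho <- sqrt(dr^2 + dc^2) / R
  theta <- atan2(dr, dc)
  N <- length(idx)
  orders <- zernike_orders(degree)
  out <- numeric(nrow(orders))
  for (k in seq_len(nrow(orders))) {
    n <- orders[k, 1]; m <- orders[k, 2]
    rad <- zernike_radial(n, m, rho)
    re <- sum(rad * cos(m * theta)) / N
    im <- sum(rad * sin(m * theta)) / N
    out[k] <- (n + 1) / pi * sqrt(re^2 + im^2)
  }
  names(out) <- sprintf("Zernike_%d_%d", orders[, 1], orders[, 2])
  out
}
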