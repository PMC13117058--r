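# Granularity spectra, radial intensity distributions and Haralick texture
# statistics for single objects.

crop_pair <- function(channel, bin, pad = 0L) {
  H <- nrow(bin)
  idx <- which(bin)
  bb <- pad_bbox(bbox_of(idx, H), pad, H, ncol(bin))
  list(channel = channel[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE],
       bin = bin[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE])
}

#' Granularity spectrum of one object in one channel
#'
#' Iterative grayscale openings with disk structuring elements of radius
#' 1..`n_scales`; element *i* is 100 times the mean intensity removed between
#' scales *i - 1* and *i* (within the object) divided by the original mean
#' intensity. A zero-mean object yields an all-zero spectrum; a constant
#' image loses nothing to opening and also yields zeros.
#'
#' @param channel Intensity matrix.
#' @param bin Logical matrix marking the object's pixels.
#' @param n_scales Number of scales (default 16).
#' @return Numeric vector of length `n_scales`.
#' @export
granularity_spectrum <- function(channel, bin, n_scales = 16L) {
  bin <- bin != 0
  if (!any(bin)) stop("empty object")
  # openings run on the local crop with surrounding context left in place
  # (a globally constant image then loses nothing at any scale); means are
  # taken within the object
  cp <- crop_pair(channel, bin, pad = n_scales + 1L)
  img <- cp$channel
  obj <- cp$bin
  orig_mean <- mean(img[obj])
  out <- numeric(n_scales)
  if (orig_mean <= 0 || max(img) <= 0) return(out)
  img <- img / max(img)   # grayscale morphology operates on [0, 1]
  orig_mean <- mean(img[obj])
  prev <- orig_mean
  for (i in seq_len(n_scales)) {
    brush <- EBImage::makeBrush(2L * i + 1L, shape = "disc")
    op <- EBImage::opening(img, brush)
    cur <- mean(matrix(op, nrow(img), ncol(img))[obj])
    out[i] <- 100 * (prev - cur) / orig_mean
    prev <- cur
  }
  out
}

#' Radial intensity distribution of one object
#'
#' Pixels are binned into `n_bins` equal-width rings of normalized radial
#' position `d_centroid / (d_centroid + d_edge)` (0 at the centroid, 1 at the
#' boundary; exact fractional radius for a disk). Per ring: `FracAtD`, the
#' fraction of total object intensity; `MeanFrac`, FracAtD divided by the
#' ring's share of the object area; and `RadialCV`, the coefficient of
#' variation of mean intensity across 8 angular wedges within the ring. A
#' zero-intensity object reports all-zero FracAtD (and MeanFrac/RadialCV 0).
#'
#' @param channel Intensity matrix.
#' @param bin Logical matrix marking the object's pixels.
#' @param n_bins Number of rings (default 4).
#' @return Named numeric vector of length `3 * n_bins`.
#' @export
radial_distribution <- function(channel, bin, n_bins = 4L) {
  bin <- bin != 0
  idx <- which(bin)
  if (!length(idx)) stop("empty object")
  H <- nrow(bin)
  co <- idx_coords(idx, H)
  mu_r <- mean(co[, 1]); mu_c <- mean(co[, 2])
  d_cen <- sqrt((co[, 1] - mu_r)^2 + (co[, 2] - mu_c)^2)
  d_edge <- object_radii(bin)        # distance to nearest background
  denom <- d_cen + d_edge
  frac <- ifelse(denom > 0, d_cen / denom, 0)
  ring <- pmin(floor(frac * n_bins) + 1L, n_bins)
  v <- channel[idx]
  tot <- sum(v)
  area <- length(idx)
  wedge <- (floor((atan2(co[, 1] - mu_r, co[, 2] - mu_c) + pi) /
                    (2 * pi) * 8) %% 8) + 1L
  fracd <- meanf <- rcv <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    sel <- ring == k
    if (!any(sel)) next
    ring_int <- sum(v[sel])
    fracd[k] <- if (tot > 0) ring_int / tot else 0
    area_frac <- sum(sel) / area
    meanf[k] <- if (area_frac > 0) fracd[k] / area_frac else 0
    wm <- tapply(v[sel], wedge[sel], mean)
    m <- mean(wm)
    rcv[k] <- if (m > 0) sqrt(mean((wm - m)^2)) / m else 0
  }
  stats::setNames(c(fracd, meanf, rcv),
                  c(sprintf("FracAtD_%dof%d", seq_len(n_bins), n_bins),
                    sprintf("MeanFrac_%dof%d", seq_len(n_bins), n_bins),
                    sprintf("RadialCV_%dof%d", seq_len(n_bins), n_bins)))
}

# normalized symmetric co-occurrence matrix for one direction; NULL when the
# direction yields no pixel pairs inside the object
glcm_direction <- function(q, obj, dr, dc, levels) {
  H <- nrow(q); W <- ncol(q)
  r1 <- seq_len(H); c1 <- seq_len(W)
  rs <- r1[r1 + dr >= 1L & r1 + dr <= H]
  cs <- c1[c1 + dc >= 1L & c1 + dc <= W]
  if (!length(rs) || !length(cs)) return(NULL)
  a_obj <- obj[rs, cs, drop = FALSE]
  b_obj <- obj[rs + dr, cs + dc, drop = FALSE]
  sel <- a_obj & b_obj
  if (!any(sel)) return(NULL)
  a <- q[rs, cs, drop = FALSE][sel]
  b <- q[rs + dr, cs + dc, drop = FALSE][sel]
  p <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 0:(levels - 1L)),
               factor(b, levels = 0:(levels - 1L)))
  p <- p + tab + t(tab)
  p / sum(p)
}

log2z <- function(x) ifelse(x > 0, log2(x), 0)

haralick_stats <- function(p) {
  L <- nrow(p)
  lev <- 0:(L - 1L)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  ij <- outer(lev, lev)
  dif <- outer(lev, lev, "-")
  asm <- sum(p^2)
  contrast <- sum(dif^2 * p)
  corr <- if (sd_x > 0 && sd_y > 0)
    (sum(ij * p) - mu_x * mu_y) / (sd_x * sd_y) else 0
  variance <- sum((outer(lev, lev, function(i, j) i) - mu_x)^2 * p)
  idm <- sum(p / (1 + dif^2))
  # p_{x+y} over k = 0..2L-2 and p_{x-y} over k = 0..L-1
  ks <- 0:(2L * L - 2L)
  sums <- outer(lev, lev, "+")
  pxy_sum <- vapply(ks, function(k) sum(p[sums == k]), numeric(1))
  kd <- 0:(L - 1L)
  pxy_dif <- vapply(kd, function(k) sum(p[abs(dif) == k]), numeric(1))
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  sum_ent <- -sum(pxy_sum * log2z(pxy_sum))
  entropy <- -sum(p * log2z(p))
  dif_mu <- sum(kd * pxy_dif)
  dif_var <- sum((kd - dif_mu)^2 * pxy_dif)
  dif_ent <- -sum(pxy_dif * log2z(pxy_dif))
  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  im1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  im2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  stats::setNames(
    c(asm, contrast, corr, variance, idm, sum_avg, sum_var, sum_ent,
      entropy, dif_var, dif_ent, im1, im2),
    .haralick_names)
}

#' Haralick texture features of one object in one channel
#'
#' Intensities within the object are linearly quantized to `levels` gray
#' levels over the object's min-max range (a constant object maps to level
#' 0); symmetric normalized co-occurrence matrices are accumulated for the
#' requested directions at the given pixel offset, only over pixel pairs that
#' both lie inside the object; the 13 Haralick statistics are computed per
#' direction and averaged (directions yielding no pairs are skipped; if none
#' yields a pair, e.g. a single-pixel object, the vector is all zeros).
#' Statistics whose definition divides by a zero variance are 0. Logarithms
#' are base 2; gray levels are indexed from 0.
#'
#' @param channel Intensity matrix.
#' @param bin Logical matrix marking the object's pixels.
#' @param levels Number of gray levels (default 8).
#' @param offset Pair offset in pixels (default 3).
#' @param directions Subset of `c("0", "45", "90", "135")` (default all 4,
#'   averaged); direction 0 pairs along rows (horizontal), 90 along columns.
#' @return Named numeric vector of length 13.
#' @export
haralick_texture <- function(channel, bin, levels = 8L, offset = 3L,
                             directions = c("0", "45", "90", "135")) {
  bin <- bin != 0
  if (!any(bin)) stop("empty object")
  stopifnot(levels >= 2L, offset >= 1L)
  cp <- crop_pair(channel, bin, pad = offset)
  v <- cp$channel[cp$bin]
  rng <- range(v)
  q <- matrix(0L, nrow(cp$bin), ncol(cp$bin))
  if (diff(rng) > 0) {
    qq <- floor((cp$channel - rng[1]) / diff(rng) * levels)
    q[] <- pmin(pmax(qq, 0L), levels - 1L)
  }
  dirs <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
               "90" = c(1L, 0L), "135" = c(1L, 1L))
  acc <- matrix(0, 0, 13)
  for (d in directions) {
    dd <- dirs[[d]] * offset
    p <- glcm_direction(q, cp$bin, dd[1], dd[2], levels)
    if (is.null(p)) next
    acc <- rbind(acc, haralick_stats(p))
  }
  if (!nrow(acc))
    return(stats::setNames(numeric(13), .haralick_names))
  stats::setNames(colMeans(acc), .haralick_names)
}
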