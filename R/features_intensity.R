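# Per-object intensity, location and channel-correlation features.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Intensity features of one object in one channel
#'
#' Integrated/Mean/Std/Min/Max/Median/MAD and lower/upper quartile intensity
#' (quantiles by linear interpolation; Std and MAD are population-style:
#' `sqrt(mean((x - mean)^2))` and the raw median absolute deviation from the
#' median), MassDisplacement (Euclidean distance between the binary centroid
#' and the intensity-weighted centroid, 0 for a zero-intensity object), and
#' the five edge variants over the object's edge pixels (object pixels with
#' at least one non-object 4-neighbour).
#'
#' @param channel Intensity matrix (same dimensions as `bin`).
#' @param bin Logical matrix marking the object's pixels.
#' @return Named numeric vector of length 15.
#' @export
intensity_features <- function(channel, bin) {
  bin <- bin != 0
  idx <- which(bin)
  if (!length(idx)) stop("empty object")
  v <- channel[idx]
  H <- nrow(bin)
  co <- idx_coords(idx, H)
  tot <- sum(v)
  md <- if (tot > 0) {
    sqrt((sum(co[, 1] * v) / tot - mean(co[, 1]))^2 +
           (sum(co[, 2] * v) / tot - mean(co[, 2]))^2)
  } else 0
  edge <- edge_pixels(bin)
  ev <- channel[edge]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(IntegratedIntensity = tot,
    MeanIntensity = mean(v),
    StdIntensity = pop_sd(v),
    MinIntensity = min(v),
    MaxIntensity = max(v),
    MedianIntensity = q[2],
    MADIntensity = stats::median(abs(v - q[2])),
    LowerQuartileIntensity = q[1],
    UpperQuartileIntensity = q[3],
    MassDisplacement = md,
    IntegratedIntensityEdge = sum(ev),
    MeanIntensityEdge = if (length(ev)) mean(ev) else 0,
    StdIntensityEdge = if (length(ev)) pop_sd(ev) else 0,
    MinIntensityEdge = if (length(ev)) min(ev) else 0,
    MaxIntensityEdge = if (length(ev)) max(ev) else 0)
}

#' Location features of one object
#'
#' The binary centroid and, per channel, the intensity-weighted centre of
#' mass (falling back to the binary centroid for a zero-intensity object) and
#' the location of the intensity maximum (first occurrence in raster order on
#' ties). X = column, Y = row, 0-based.
#'
#' @param stack A [channel_stack()] or a named list of intensity matrices.
#' @param bin Logical matrix marking the object's pixels.
#' @param offset 0-based (row, col) offset of `bin` within the full scene.
#' @return Named numeric vector of length `2 + 4 * C`.
#' @export
location_features <- function(stack, bin, offset = c(0, 0)) {
  bin <- bin != 0
  idx <- which(bin)
  if (!length(idx)) stop("empty object")
  H <- nrow(bin)
  co <- idx_coords(idx, H)
  mu_r <- mean(co[, 1]); mu_c <- mean(co[, 2])
  channels <- if (inherits(stack, "channel_stack")) {
    stats::setNames(lapply(stack$channel_names, function(ch)
      get_channel(stack, ch)), stack$channel_names)
  } else stack
  out <- c(Location_Center_X = mu_c + offset[2],
           Location_Center_Y = mu_r + offset[1])
  W <- ncol(bin)
  raster_key <- co[, 1] * W + co[, 2]
  for (nm in names(channels)) {
    v <- channels[[nm]][idx]
    tot <- sum(v)
    if (tot > 0) {
      cmr <- sum(co[, 1] * v) / tot; cmc <- sum(co[, 2] * v) / tot
    } else { cmr <- mu_r; cmc <- mu_c }
    mx <- which(v == max(v))
    best <- mx[which.min(raster_key[mx])]
    res <- c(cmc + offset[2], cmr + offset[1],
             co[best, 2] + offset[2], co[best, 1] + offset[1])
    names(res) <- sprintf("Location_%s_%s",
                          c("CenterMassIntensity_X", "CenterMassIntensity_Y",
                            "MaxIntensity_X", "MaxIntensity_Y"), nm)
    out <- c(out, res)
  }
  out
}

#' Colocalization features between two channels within one object
#'
#' Pearson correlation (0 when either channel has zero variance within the
#' object), the least-squares slope of b on a and of a on b, the overlap
#' coefficient, Manders coefficients M1/M2 (per-channel Otsu thresholds
#' within the object), and the intensity-fraction coefficients K1/K2. All
#' ratios with zero denominators are defined as 0.
#'
#' @param channel_a,channel_b Intensity matrices.
#' @param bin Logical matrix marking the object's pixels (>= 2 pixels).
#' @return Named numeric vector of length 8.
#' @export
correlation_features <- function(channel_a, channel_b, bin) {
  bin <- bin != 0
  idx <- which(bin)
  if (length(idx) < 2L) stop("correlation features need >= 2 object pixels")
  a <- channel_a[idx]; b <- channel_b[idx]
  va <- stats::var(a); vb <- stats::var(b)
  r <- if (va > 0 && vb > 0) stats::cor(a, b) else 0
  cv <- if (va > 0 || vb > 0) stats::cov(a, b) else 0
  slope <- if (va > 0) cv / va else 0
  slope_sw <- if (vb > 0) cv / vb else 0
  sab <- sum(a * b); saa <- sum(a^2); sbb <- sum(b^2)
  overlap <- if (saa > 0 && sbb > 0) sab / sqrt(saa * sbb) else 0
  norm01v <- function(x) if (max(x) > 0) x / max(x) else x
  ta <- otsu_threshold(norm01v(a))
  tb <- otsu_threshold(norm01v(b))
  m1 <- if (sum(a) > 0) sum(a[norm01v(b) > tb]) / sum(a) else 0
  m2 <- if (sum(b) > 0) sum(b[norm01v(a) > ta]) / sum(b) else 0
  c(Correlation = r,
    Slope = slope,
    SlopeSwapped = slope_sw,
    Overlap = overlap,
    MandersM1 = m1,
    MandersM2 = m2,
    K1 = if (saa > 0) sab / saa else 0,
    K2 = if (sbb > 0) sab / sbb else 0)
}
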