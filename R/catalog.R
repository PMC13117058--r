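#' Feature catalog
#'
#' A feature catalog is the deterministic, configuration-driven list of
#' per-object feature columns: which groups are measured, on which channels
#' or channel pairs, with which parameters (Zernike degree, granularity
#' scales, radial bins, texture levels/offsets, neighbor distance) and for
#' which compartments. Column order is fixed given the configuration, and the
#' total column count has a closed form (see [catalog_ncol()]).
#'
#' Per-group column counts for C channels: AreaShape 25 + Zernike moments
#' (30 at degree 9); Intensity 15 C; Location 2 + 4 C; Correlation 8 per
#' unordered channel pair; Granularity `n_scales` C; RadialDistribution
#' `3 n_bins` C; Neighbors 5; Texture `13 C |offsets|`.
#'
#' @param channels Character vector of channel names measured.
#' @param compartments Subset of `c("cell", "nucleus", "cytoplasm")`.
#' @param zernike_degree Maximum Zernike order (default 9, giving 30
#'   magnitudes).
#' @param granularity_scales Number of granularity spectrum scales
#'   (default 16).
#' @param radial_bins Number of radial distribution rings (default 4).
#' @param texture_levels Gray levels for co-occurrence quantization
#'   (default 8).
#' @param texture_offsets Integer vector of co-occurrence offsets in pixels
#'   (default 3).
#' @param neighbor_distance Neighborhood expansion distance in pixels
#'   (default 5).
#' @param groups Which feature groups to include (default all eight).
#' @return Object of class `feature_catalog`.
#' @export
feature_catalog <- function(channels = .default_channels[1:5],
                            compartments = c("cell", "nucleus", "cytoplasm"),
                            zernike_degree = 9L,
                            granularity_scales = 16L,
                            radial_bins = 4L,
                            texture_levels = 8L,
                            texture_offsets = 3L,
                            neighbor_distance = 5L,
                            groups = c("AreaShape", "Correlation",
                                       "Granularity", "Intensity", "Location",
                                       "Neighbors", "RadialDistribution",
                                       "Texture")) {
  compartments <- match.arg(compartments,
                            c("cell", "nucleus", "cytoplasm"),
                            several.ok = TRUE)
  stopifnot(zernike_degree >= 0, granularity_scales >= 1, radial_bins >= 1,
            texture_levels >= 2, all(texture_offsets >= 1),
            neighbor_distance >= 1, length(channels) >= 1)
  structure(list(channels = channels, compartments = compartments,
                 zernike_degree = as.integer(zernike_degree),
                 granularity_scales = as.integer(granularity_scales),
                 radial_bins = as.integer(radial_bins),
                 texture_levels = as.integer(texture_levels),
                 texture_offsets = as.integer(texture_offsets),
                 neighbor_distance = as.integer(neighbor_distance),
                 groups = groups),
            class = "feature_catalog")
}

zernike_orders <- function(degree) {
  out <- NULL
  for (n in 0:degree) for (m in seq(n %% 2, n, by = 2))
    out <- rbind(out, c(n, m))
  colnames(out) <- c("n", "m")
  out
}

.areashape_names <- c(
  "Area", "Perimeter", "FormFactor", "Eccentricity", "MajorAxisLength",
  "MinorAxisLength", "Orientation", "Solidity", "Extent",
  "EquivalentDiameter", "Compactness", "EulerNumber", "ConvexArea",
  "BoundingBoxArea", "BoundingBoxWidth", "BoundingBoxHeight",
  "BoundingBoxMinRow", "BoundingBoxMinCol",
  "MaxFeretDiameter", "MinFeretDiameter",
  "MeanRadius", "MedianRadius", "MaximumRadius", "CenterRow", "CenterCol")

.intensity_names <- c(
  "IntegratedIntensity", "MeanIntensity", "StdIntensity", "MinIntensity",
  "MaxIntensity", "MedianIntensity", "MADIntensity", "LowerQuartileIntensity",
  "UpperQuartileIntensity", "MassDisplacement",
  "IntegratedIntensityEdge", "MeanIntensityEdge", "StdIntensityEdge",
  "MinIntensityEdge", "MaxIntensityEdge")

.correlation_names <- c("Correlation", "Slope", "SlopeSwapped", "Overlap",
                        "MandersM1", "MandersM2", "K1", "K2")

.haralick_names <- c(
  "AngularSecondMoment", "Contrast", "Correlation", "Variance",
  "InverseDifferenceMoment", "SumAverage", "SumVariance", "SumEntropy",
  "Entropy", "DifferenceVariance", "DifferenceEntropy", "InfoMeas1",
  "InfoMeas2")

.neighbor_names <- c("NumberOfNeighbors", "PercentTouching",
                     "FirstClosestDistance", "SecondClosestDistance",
                     "AngleBetweenNeighbors")

channel_pairs <- function(channels) {
  if (length(channels) < 2L)
    return(matrix(character(0), 0, 2))
  t(utils::combn(channels, 2L))
}

#' Enumerate the catalog's feature column names
#'
#' @param catalog A [feature_catalog()].
#' @return Character vector of column names, in deterministic order.
#' @export
catalog_columns <- function(catalog) {
  ch <- catalog$channels
  cols <- character(0)
  g <- catalog$groups
  if ("AreaShape" %in% g) {
    zo <- zernike_orders(catalog$zernike_degree)
    cols <- c(cols, paste0("AreaShape_", .areashape_names),
              sprintf("AreaShape_Zernike_%d_%d", zo[, 1], zo[, 2]))
  }
  if ("Correlation" %in% g) {
    cp <- channel_pairs(ch)
    if (nrow(cp))
      cols <- c(cols, as.vector(t(outer(
        seq_len(nrow(cp)), .correlation_names,
        function(i, nm) sprintf("Correlation_%s_%s_%s", nm, cp[i, 1], cp[i, 2])))))
  }
  if ("Granularity" %in% g)
    cols <- c(cols, as.vector(vapply(ch, function(c0)
      sprintf("Granularity_%d_%s", seq_len(catalog$granularity_scales), c0),
      character(catalog$granularity_scales))))
  if ("Intensity" %in% g)
    cols <- c(cols, as.vector(vapply(ch, function(c0)
      sprintf("Intensity_%s_%s", .intensity_names, c0),
      character(length(.intensity_names)))))
  if ("Location" %in% g) {
    cols <- c(cols, "Location_Center_X", "Location_Center_Y")
    cols <- c(cols, as.vector(vapply(ch, function(c0)
      sprintf("Location_%s_%s",
              c("CenterMassIntensity_X", "CenterMassIntensity_Y",
                "MaxIntensity_X", "MaxIntensity_Y"), c0), character(4))))
  }
  if ("Neighbors" %in% g)
    cols <- c(cols, sprintf("Neighbors_%s_%d", .neighbor_names,
                            catalog$neighbor_distance))
  if ("RadialDistribution" %in% g)
    for (c0 in ch)
      for (nm in c("FracAtD", "MeanFrac", "RadialCV"))
        cols <- c(cols, sprintf("RadialDistribution_%s_%s_%dof%d", nm, c0,
                                seq_len(catalog$radial_bins),
                                catalog$radial_bins))
  if ("Texture" %in% g)
    for (c0 in ch)
      for (off in catalog$texture_offsets)
        cols <- c(cols, sprintf("Texture_%s_%s_%d", .haralick_names, c0, off))
  cols
}

#' Closed-form catalog column count
#'
#' @param catalog A [feature_catalog()].
#' @return Integer column count implied by the configuration (without
#'   enumerating columns).
#' @export
catalog_ncol <- function(catalog) {
  C <- length(catalog$channels)
  g <- catalog$groups
  n <- 0L
  if ("AreaShape" %in% g)
    n <- n + 25L + nrow(zernike_orders(catalog$zernike_degree))
  if ("Correlation" %in% g) n <- n + 8L * choose(C, 2L)
  if ("Granularity" %in% g) n <- n + catalog$granularity_scales * C
  if ("Intensity" %in% g) n <- n + 15L * C
  if ("Location" %in% g) n <- n + 2L + 4L * C
  if ("Neighbors" %in% g) n <- n + 5L
  if ("RadialDistribution" %in% g) n <- n + 3L * catalog$radial_bins * C
  if ("Texture" %in% g)
    n <- n + 13L * C * length(catalog$texture_offsets)
  as.integer(n)
}

#' Feature group of each column name
#'
#' @param columns Character vector of feature column names
#'   (`Group_Name_...`).
#' @return Character vector of group labels (text before the first
#'   underscore).
#' @export
feature_groups_of <- function(columns) {
  sub("_.*$", "", columns)
}
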