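#' Confidence-map containers
#'
#' Per-class pixel probability maps: a class map scoring object interiors and
#' a border map scoring object boundaries, both in `[0, 1]` and sharing
#' dimensions. A full set holds one pair per segmentation class
#' (cell, nucleus).
#'
#' @param class_map H x W matrix in `[0, 1]`.
#' @param border_map H x W matrix in `[0, 1]`.
#' @return Object of class `confidence_pair`.
#' @export
confidence_pair <- function(class_map, border_map) {
  class_map <- as.matrix(class_map); border_map <- as.matrix(border_map)
  check_same_dim(class_map, border_map, "class and border maps")
  rng <- range(class_map, border_map)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("confidence values must lie in [0, 1], got range [",
         rng[1], ", ", rng[2], "]")
  structure(list(class_map = pmin(pmax(class_map, 0), 1),
                 border_map = pmin(pmax(border_map, 0), 1)),
            class = "confidence_pair")
}

#' @param cell,nucleus [confidence_pair()] objects.
#' @rdname confidence_pair
#' @export
confidence_maps <- function(cell, nucleus) {
  stopifnot(inherits(cell, "confidence_pair"),
            inherits(nucleus, "confidence_pair"))
  check_same_dim(cell$class_map, nucleus$class_map, "cell and nucleus maps")
  structure(list(cell = cell, nucleus = nucleus), class = "confidence_maps")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# histogram Otsu threshold on values in [0, 1]
otsu_threshold <- function(v, breaks = 256L) {
  v <- v[is.finite(v)]
  if (!length(v) || diff(range(v)) == 0) return(max(v, 0))
  h <- tabulate(pmin(pmax(findInterval(v, seq(0, 1, length.out = breaks + 1L),
                                       rightmost.closed = TRUE), 1L), breaks),
                breaks)
  p <- h / sum(h)
  mids <- (seq_len(breaks) - 0.5) / breaks
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[breaks]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

grad_magnitude <- function(x) {
  sob <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gr <- EBImage::filter2(x, sob, boundary = "replicate")
  gc <- EBImage::filter2(x, t(sob), boundary = "replicate")
  sqrt(gr^2 + gc^2)
}

#' Classical baseline confidence maps from a channel stack
#'
#' A classical generator of class/border confidence maps, so the segmentation
#' and refinement stages can run without a trained model: nuclei are scored
#' from the DNA channel, cells from the pixelwise maximum of RNA and DNA
#' (nucleoli/cytoplasmic RNA delineates the cell body; DNA guarantees the
#' nucleus is included). Each channel is Gaussian-smoothed, rescaled to
#' `[0, 1]` and passed through a soft threshold centred on its Otsu level;
#' border maps are the max-normalized gradient magnitude of the class map.
#' Externally produced maps (e.g. from a trained network) can be supplied to
#' [instances_from_confidence()] directly instead.
#'
#' @param stack [channel_stack()] containing DNA and RNA channels.
#' @param smoothing_sigma Gaussian sigma in pixels (default 2).
#' @return A [confidence_maps()] object.
#' @export
baseline_confidence_maps <- function(stack, smoothing_sigma = 2) {
  dna <- get_channel(stack, "DNA")
  rna <- get_channel(stack, "RNA")
  soft_class <- function(ch) {
    m <- max(ch)
    x <- if (m > 0) ch / m else ch
    if (smoothing_sigma > 0) x <- EBImage::gblur(x, sigma = smoothing_sigma)
    x <- clip01(matrix(x, nrow(ch), ncol(ch)))
    if (max(x) == 0) return(x)
    t <- otsu_threshold(as.vector(x))
    clip01(0.5 + (x - t) / (2 * max(t, 1e-6)))
  }
  border_of <- function(cm) {
    g <- grad_magnitude(cm)
    m <- max(g)
    clip01(matrix(if (m > 0) g / m else g, nrow(cm), ncol(cm)))
  }
  nuc <- soft_class(dna)
  cel <- soft_class(pmax(rna, dna))
  confidence_maps(cell = confidence_pair(cel, border_of(cel)),
                  nucleus = confidence_pair(nuc, border_of(nuc)))
}

#' Instance segmentation from confidence maps
#'
#' Watershed-style post-processing of a class/border confidence pair:
#' foreground is the class map thresholded at `class_threshold`; seed markers
#' are 4-connected components of pixels where the class map exceeds the
#' border map by at least `seed_margin` (inside the foreground); the border
#' map is then flooded from the seeds within the foreground, each seed
#' yielding one instance. Foreground components unreachable from any seed
#' become instances of their own. Labels are renumbered 1..N in raster order.
#'
#' @param maps A [confidence_pair()] (or a [confidence_maps()] plus `class`).
#' @param class_threshold Foreground threshold in (0, 1); default 0.5.
#' @param seed_margin Required class-minus-border margin for seeds;
#'   default 0.3.
#' @param class For a full [confidence_maps()] input, which pair to segment
#'   (`"cell"` or `"nucleus"`).
#' @return Integer label mask.
#' @export
instances_from_confidence <- function(maps, class_threshold = 0.5,
                                      seed_margin = 0.3,
                                      class = c("cell", "nucleus")) {
  if (inherits(maps, "confidence_maps")) {
    class <- match.arg(class)
    maps <- maps[[class]]
  }
  stopifnot(inherits(maps, "confidence_pair"))
  if (class_threshold <= 0 || class_threshold >= 1)
    stop("class_threshold must lie strictly between 0 and 1")
  cm <- maps$class_map; bm <- maps$border_map
  fg <- cm >= class_threshold
  if (!any(fg)) return(matrix(0L, nrow(cm), ncol(cm)))
  seeds <- cc_label((cm - bm >= seed_margin) & fg)
  if (max(seeds) > 0L) {
    lab <- EBImage::propagate(bm, seeds,
                              mask = matrix(as.numeric(fg), nrow(fg), ncol(fg)),
                              lambda = 1e-4)
    lab <- as_label_matrix(matrix(lab, nrow(cm), ncol(cm)))
  } else {
    lab <- matrix(0L, nrow(cm), ncol(cm))
  }
  orphan <- fg & lab == 0L
  if (any(orphan)) {
    extra <- cc_label(orphan)
    lab[orphan] <- extra[orphan] + max(lab)
  }
  renumber_raster(lab)
}

#' Segment a scene into cell and nucleus masks
#'
#' Convenience wrapper running [instances_from_confidence()] for both classes.
#' In `cell_mode = "semantic"` the cell class map is treated as a single
#' semantic foreground (connected components only, no seed splitting), to be
#' partitioned into instances downstream by nucleus-guided refinement; this
#' mirrors pairing semantic cell output with instance nucleus output.
#'
#' @param maps [confidence_maps()].
#' @param class_threshold,seed_margin See [instances_from_confidence()].
#' @param cell_mode `"instance"` or `"semantic"`.
#' @return List with integer masks `cells` and `nuclei`.
#' @export
segment_scene <- function(maps, class_threshold = 0.5, seed_margin = 0.3,
                          cell_mode = c("instance", "semantic")) {
  cell_mode <- match.arg(cell_mode)
  nuclei <- instances_from_confidence(maps$nucleus, class_threshold,
                                      seed_margin)
  if (cell_mode == "instance") {
    cells <- instances_from_confidence(maps$cell, class_threshold, seed_margin)
  } else {
    cells <- renumber_raster(cc_label(maps$cell$class_map >= class_threshold))
  }
  list(cells = cells, nuclei = nuclei)
}

#' Read / write confidence maps as float TIFF
#'
#' Maps are stored as 32-bit float TIFF in `[0, 1]`; 8/16-bit integer input
#' is normalized by its bit-depth maximum.
#'
#' @param path File path.
#' @param x Matrix in `[0, 1]` (for writing).
#' @export
read_confidence_map <- function(path) {
  # float samples come back as stored; integer samples are normalized to
  # [0, 1] by their bit-depth maximum (readTIFF's default), matching the
  # "16-bit with max = 1.0 after division by 65535" on-disk convention
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  clip01(matrix(as.numeric(img), nrow(img), ncol(img)))
}

#' @rdname read_confidence_map
#' @export
write_confidence_map <- function(x, path) {
  tiff::writeTIFF(pmin(pmax(x, 0), 1), path, bits.per.sample = 32L,
                  reduce = TRUE)
  invisible(path)
}
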