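# Seeded generator of synthetic Cell Painting-like scenes with complete
# ground truth: elliptical cells with interior nuclei, channel-specific
# staining, Poisson-Gaussian noise, outline images, ideal confidence maps
# and instance label masks.

# deterministic 32-bit stream seed from (seed, plate, well, site); stays
# below 2^31
scene_stream_seed <- function(seed, coord = NULL) {
  h <- as.double(seed) %% 2147483647
  if (!is.null(coord)) {
    s <- format(coord)
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Default parameters for synthetic scene generation
#'
#' Canvas and population defaults emulate a (down-scaled) Cell Painting
#' field: a 512 x 512 16-bit canvas, around 12 well-separated elliptical
#' cells with semi-axes 18-30 px, each containing one interior nucleus at
#' 35-55% of the cell's scale, Poisson shot noise on the rendered signal
#' plus additive Gaussian read noise (sigma 100 on the 16-bit scale).
#'
#' @param ... Overrides of the default parameter list.
#' @return Named list of generation parameters.
#' @export
scene_params <- function(...) {
  p <- list(size = 512L, n_cells = 12L,
            cell_axis_range = c(18, 30),
            nucleus_scale_range = c(0.35, 0.55),
            min_gap = 3,
            multi_nucleate_fraction = 0,
            fragment_fraction = 0,
            fragment_axis_range = c(3, 5),
            noise = "poisson-gaussian",   # or "none"
            gaussian_sd = 100,
            confidence_blur_sigma = 0,
            max_retries = 200L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown scene parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

# rasterize an ellipse: centre (r0, c0) 0-based, semi-axes (a, b) along the
# rotated frame, rotation theta; returns linear indices into an H x W matrix
ellipse_indices <- function(r0, c0, a, b, theta, H, W) {
  rr <- max(a, b)
  rows <- max(1L, floor(r0 - rr)):min(H, ceiling(r0 + rr + 2))
  cols <- max(1L, floor(c0 - rr)):min(W, ceiling(c0 + rr + 2))
  pr <- rep(rows - 1L, times = length(cols))
  pc <- rep(cols - 1L, each = length(rows))
  dr <- pr - r0; dc <- pc - c0
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  (pc[sel]) * H + pr[sel] + 1L
}

#' Generate a synthetic Cell Painting-like scene with ground truth
#'
#' Places non-overlapping elliptical cells, each containing one interior
#' elliptical nucleus (a configurable fraction receive two, for testing the
#' splitting of multi-nucleated detections; nuclei always lie entirely
#' within their parent cell by construction). An optional fraction of small
#' anucleate "fragments" emulates debris/false detections: they are rendered
#' into the image and into the cell-class confidence maps, but kept in a
#' separate label mask (`fragments`) rather than the ground-truth cell mask.
#' Channels are rendered with compartment-specific staining (DNA bright in
#' nuclei; RNA in cytoplasm and nuclei; ER/AGP/Mito as textured cytoplasmic
#' signal; three brightfield planes as edge-weighted gradients), then
#' Poisson-Gaussian noise is applied and clipped to the 16-bit range.
#' Everything is reproducible from `(seed, coord)`: one pseudo-random stream
#' is derived per scene.
#'
#' @param params Parameter list from [scene_params()].
#' @param seed Integer seed.
#' @param coord Optional [plate_coord()]; folded into the stream seed so
#'   manifests of scenes are element-wise reproducible.
#' @return A `scene_truth` list: `stack` ([channel_stack()]), `cells`,
#'   `nuclei`, `fragments` (label masks), `cells_with_artifacts` (cells plus
#'   fragment labels, the raw-detection surrogate), `outlines` (per
#'   compartment), `confidence` ([confidence_maps()], ideal), and `params`
#'   with the realized placement counts.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L, coord = NULL) {
  stopifnot(params$size >= 64L, params$n_cells >= 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scene_stream_seed(seed, coord))
  H <- W <- as.integer(params$size)
  cells <- matrix(0L, H, W)
  nuclei <- matrix(0L, H, W)
  placed <- list()
  n_target <- params$n_cells
  n_multi <- round(params$multi_nucleate_fraction * n_target)
  tries <- 0L
  while (length(placed) < n_target && tries < params$max_retries * max(n_target, 1L)) {
    tries <- tries + 1L
    a <- stats::runif(1, params$cell_axis_range[1], params$cell_axis_range[2])
    b <- stats::runif(1, params$cell_axis_range[1], params$cell_axis_range[2])
    theta <- stats::runif(1, 0, pi)
    rr <- max(a, b) + params$min_gap
    r0 <- stats::runif(1, rr + 1, H - rr - 2)
    c0 <- stats::runif(1, rr + 1, W - rr - 2)
    ok <- TRUE
    for (q in placed) {
      if (sqrt((q$r0 - r0)^2 + (q$c0 - c0)^2) <
          max(q$a, q$b) + max(a, b) + params$min_gap) { ok <- FALSE; break }
    }
    if (!ok) next
    placed[[length(placed) + 1L]] <- list(r0 = r0, c0 = c0, a = a, b = b,
                                          theta = theta)
  }
  n_real <- length(placed)
  nuc_label <- 0L
  for (i in seq_len(n_real)) {
    p <- placed[[i]]
    cells[ellipse_indices(p$r0, p$c0, p$a, p$b, p$theta, H, W)] <- i
    two <- i <= min(n_multi, n_real)
    k <- if (two) 2L else 1L
    s <- stats::runif(1, params$nucleus_scale_range[1],
                      params$nucleus_scale_range[2])
    if (two) s <- min(s, 0.4)   # leave room for two
    for (j in seq_len(k)) {
      # nucleus as a disk of radius s in the cell's normalized frame,
      # centre offset |o| <= 1 - s - margin: containment by construction
      omax <- max(1 - s - 0.05, 0)
      olen <- if (two) omax * 0.9 else stats::runif(1, 0, omax)
      oang <- if (two) (j - 1) * pi + p$theta else stats::runif(1, 0, 2 * pi)
      ou <- olen * cos(oang); ov <- olen * sin(oang)
      # map normalized offset back to pixel coordinates
      dc <- ou * p$a * cos(p$theta) - ov * p$b * sin(p$theta)
      dr <- ou * p$a * sin(p$theta) + ov * p$b * cos(p$theta)
      nuc_label <- nuc_label + 1L
      nuclei[ellipse_indices(p$r0 + dr, p$c0 + dc, s * p$a, s * p$b,
                             p$theta, H, W)] <- nuc_label
    }
  }
  # anucleate fragments: small ellipses, non-overlapping with everything
  fragments <- matrix(0L, H, W)
  n_frag_target <- round(params$fragment_fraction * n_target)
  frag_placed <- 0L
  tries <- 0L
  while (frag_placed < n_frag_target && tries < params$max_retries * 10L) {
    tries <- tries + 1L
    a <- stats::runif(1, params$fragment_axis_range[1],
                      params$fragment_axis_range[2])
    b <- stats::runif(1, params$fragment_axis_range[1],
                      params$fragment_axis_range[2])
    theta <- stats::runif(1, 0, pi)
    rr <- max(a, b) + params$min_gap
    r0 <- stats::runif(1, rr + 1, H - rr - 2)
    c0 <- stats::runif(1, rr + 1, W - rr - 2)
    idx <- ellipse_indices(r0, c0, a, b, theta, H, W)
    # keep a clear gap to cells and other fragments
    bb <- pad_bbox(bbox_of(idx, H), as.integer(ceiling(params$min_gap)), H, W)
    zone <- cells[bb[1]:bb[2], bb[3]:bb[4]] | fragments[bb[1]:bb[2], bb[3]:bb[4]]
    if (any(zone)) next
    frag_placed <- frag_placed + 1L
    fragments[idx] <- frag_placed
  }
  cells_art <- cells
  cells_art[fragments > 0L] <- fragments[fragments > 0L] + n_real
  stack <- render_channels(cells, nuclei, fragments, params)
  conf <- ideal_confidence_maps(cells_art, nuclei,
                                blur_sigma = params$confidence_blur_sigma)
  params$n_cells_realized <- n_real
  params$n_multi_realized <- min(n_multi, n_real)
  params$n_fragments_realized <- frag_placed
  params$seed <- seed
  structure(list(stack = stack, cells = cells, nuclei = nuclei,
                 fragments = fragments, cells_with_artifacts = cells_art,
                 outlines = list(cell = draw_outlines(cells),
                                 nucleus = draw_outlines(nuclei)),
                 confidence = conf, params = params, coord = coord),
            class = "scene_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

render_channels <- function(cells, nuclei, fragments, params) {
  H <- nrow(cells); W <- ncol(cells)
  nuc <- nuclei > 0L
  body <- cells > 0L | fragments > 0L
  cyto <- body & !nuc
  tex <- function(lo, hi) matrix(stats::runif(H * W, lo, hi), H, W)
  base <- 300
  sig <- list()
  sig$DNA <- base + 28000 * nuc * tex(0.85, 1.15)
  sig$RNA <- base + 11000 * cyto * tex(0.8, 1.2) + 17000 * nuc * tex(0.85, 1.15)
  sig$ER <- base + 9000 * cyto * tex(0.55, 1.45) + 2500 * nuc
  sig$AGP <- base + 8000 * cyto * tex(0.5, 1.5) + 1500 * nuc
  sig$Mito <- base + 10000 * cyto * tex(0.45, 1.55) + 1000 * nuc
  # brightfield: mid-gray with edge-weighted darkening near object borders
  dist_in <- EBImage::distmap(matrix(as.numeric(body), H, W))
  dist_in <- matrix(dist_in, H, W)
  edge_w <- exp(-pmax(dist_in - 1, 0) / 3) * body
  for (i in 1:3)
    sig[[paste0("BF", i)]] <- 20000 + 6000 * (i - 2) / 2 - 12000 * edge_w
  px <- array(0, c(H, W, 8))
  for (i in seq_along(.default_channels)) {
    s <- pmax(sig[[.default_channels[i]]], 0)
    out <- if (identical(params$noise, "none")) s else {
      shot <- stats::rpois(length(s), lambda = as.vector(s) / 4) * 4
      shot + stats::rnorm(length(s), 0, params$gaussian_sd)
    }
    px[, , i] <- matrix(pmin(pmax(round(out), 0), 65535), H, W)
  }
  channel_stack(px, .default_channels)
}

#' Ideal confidence maps from ground-truth masks
#'
#' Class maps are 1 inside objects and 0 elsewhere; border maps are 1 on the
#' 1-px instance boundaries. Optionally Gaussian-blurred (and renormalized to
#' max 1) to emulate soft network output.
#'
#' @param cells,nuclei Integer label masks.
#' @param blur_sigma Gaussian sigma in pixels (0 = crisp).
#' @return A [confidence_maps()] object.
#' @export
ideal_confidence_maps <- function(cells, nuclei, blur_sigma = 0) {
  pair_of <- function(mask) {
    cls <- matrix(as.numeric(mask > 0L), nrow(mask), ncol(mask))
    bor <- matrix(as.numeric(label_boundaries(mask)), nrow(mask), ncol(mask))
    if (blur_sigma > 0) {
      soften <- function(x) {
        x <- EBImage::gblur(x, sigma = blur_sigma)
        m <- max(x)
        clip01(matrix(if (m > 0) x / m else x, nrow(mask), ncol(mask)))
      }
      cls <- soften(cls); bor <- soften(bor)
    }
    confidence_pair(cls, bor)
  }
  confidence_maps(cell = pair_of(cells), nucleus = pair_of(nuclei))
}

#' Degrade a ground-truth cell mask by merging neighboring cells
#'
#' Produces the classic split-and-merge failure mode for refinement tests:
#' `n_pairs` mutually closest cell pairs are fused into single labels (the
#' lower label absorbs the higher; a thin bridge is drawn between the two
#' cells along the centroid line so the merged detection is one connected
#' region, as a merged network prediction would be).
#'
#' @param cells Ground-truth cell label mask.
#' @param n_pairs Number of pairs to merge.
#' @return List with the degraded `cells` mask and the data frame `merged`
#'   of (kept, absorbed) label pairs.
#' @export
merge_cell_pairs <- function(cells, n_pairs = 1L) {
  cells <- as_label_matrix(cells)
  ids <- label_ids(cells)
  cen <- label_centroids(cells)
  out <- cells
  merged <- NULL
  used <- integer(0)
  d <- as.matrix(stats::dist(cen))
  diag(d) <- Inf
  for (k in seq_len(n_pairs)) {
    free <- setdiff(seq_along(ids), used)
    if (length(free) < 2L) break
    dd <- d[free, free, drop = FALSE]
    w <- arrayInd(which.min(dd), dim(dd))
    i <- free[w[1]]; j <- free[w[2]]
    keep <- min(ids[i], ids[j]); absorb <- max(ids[i], ids[j])
    out[out == absorb] <- keep
    # bridge along the centroid segment (3 px wide) restricted to background
    p1 <- cen[i, ]; p2 <- cen[j, ]
    L <- ceiling(sqrt(sum((p1 - p2)^2))) * 2L
    ts <- seq(0, 1, length.out = max(L, 2L))
    for (t in ts) {
      r <- p1[1] + t * (p2[1] - p1[1]); c <- p1[2] + t * (p2[2] - p1[2])
      rows <- pmin(pmax(round(r) + (-1:1), 0), nrow(out) - 1L)
      cols <- pmin(pmax(round(c) + (-1:1), 0), ncol(out) - 1L)
      for (rr in rows) for (cc in cols)
        if (out[rr + 1L, cc + 1L] == 0L) out[rr + 1L, cc + 1L] <- keep
    }
    used <- c(used, i, j)
    merged <- rbind(merged, data.frame(kept = keep, absorbed = absorb))
  }
  list(cells = out, merged = merged)
}

#' Naive oracle features computed by per-pixel loops
#'
#' An independent brute-force computation of a small feature subset (Area,
#' IntegratedIntensity, MeanIntensity, MaxIntensity, Centroid,
#' PearsonCorrelation of DNA vs RNA), sharing no code with the feature
#' extractors; used to cross-check the fast paths.
#'
#' @param scene A `scene_truth`.
#' @param subset Character vector of oracle feature names.
#' @param mask Which mask to measure (`"cells"` or `"nuclei"`).
#' @return Data frame, one row per object.
#' @export
oracle_features <- function(scene,
                            subset = c("Area", "IntegratedIntensity",
                                       "MeanIntensity", "MaxIntensity",
                                       "Centroid", "PearsonCorrelation"),
                            mask = c("cells", "nuclei")) {
  mask <- match.arg(mask)
  allowed <- c("Area", "IntegratedIntensity", "MeanIntensity", "MaxIntensity",
               "Centroid", "PearsonCorrelation")
  bad <- setdiff(subset, allowed)
  if (length(bad))
    stop("unsupported oracle feature(s): ", paste(bad, collapse = ", "))
  m <- scene[[mask]]
  dna <- get_channel(scene$stack, "DNA")
  rna <- get_channel(scene$stack, "RNA")
  ids <- sort(unique(m[m > 0]))
  rows <- list()
  for (id in ids) {
    acc <- list(object_id = id)
    n <- 0; s_dna <- 0; mx <- -Inf; sr <- 0; sc <- 0
    xs <- c(); ys <- c()
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      if (m[r, c] != id) next
      n <- n + 1
      s_dna <- s_dna + dna[r, c]
      if (dna[r, c] > mx) mx <- dna[r, c]
      sr <- sr + (r - 1); sc <- sc + (c - 1)
      xs <- c(xs, dna[r, c]); ys <- c(ys, rna[r, c])
    }
    if ("Area" %in% subset) acc$Area <- n
    if ("IntegratedIntensity" %in% subset) acc$IntegratedIntensity <- s_dna
    if ("MeanIntensity" %in% subset) acc$MeanIntensity <- s_dna / n
    if ("MaxIntensity" %in% subset) acc$MaxIntensity <- mx
    if ("Centroid" %in% subset) {
      acc$CentroidRow <- sr / n; acc$CentroidCol <- sc / n
    }
    if ("PearsonCorrelation" %in% subset) {
      mx_ <- mean(xs); my_ <- mean(ys)
      num <- sum((xs - mx_) * (ys - my_))
      den <- sqrt(sum((xs - mx_)^2) * sum((ys - my_)^2))
      acc$PearsonCorrelation <- if (den > 0) num / den else 0
    }
    rows[[length(rows) + 1L]] <- as.data.frame(acc)
  }
  do.call(rbind, rows)
}

#' Write a scene to disk in the on-disk dataset layout
#'
#' Creates `<dir>/<image-name>/` containing per-channel 16-bit TIFFs, outline
#' PNGs, ground-truth label masks and ideal confidence maps, mirroring the
#' layout the pipeline consumes.
#'
#' @param scene A `scene_truth`.
#' @param dir Output directory.
#' @return The scene directory path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  nm <- if (!is.null(scene$coord)) format(scene$coord) else "scene"
  sd <- file.path(dir, nm)
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  for (ch in scene$stack$channel_names)
    tiff::writeTIFF(get_channel(scene$stack, ch) / 65535,
                    file.path(sd, paste0(ch, ".tiff")), bits.per.sample = 16L)
  png::writePNG(scene$outlines$cell / 255,
                file.path(sd, "outlines_cell.png"))
  png::writePNG(scene$outlines$nucleus / 255,
                file.path(sd, "outlines_nucleus.png"))
  write_mask(scene$cells, file.path(sd, "truth_cells.tiff"))
  write_mask(scene$nuclei, file.path(sd, "truth_nuclei.tiff"))
  for (cls in c("cell", "nucleus")) {
    write_confidence_map(scene$confidence[[cls]]$class_map,
                         file.path(sd, paste0("confidence_", cls, "_class.tiff")))
    write_confidence_map(scene$confidence[[cls]]$border_map,
                         file.path(sd, paste0("confidence_", cls, "_border.tiff")))
  }
  invisible(sd)
}
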