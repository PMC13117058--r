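#' Plate coordinates
#'
#' A plate coordinate identifies a single field of view on a 384-well plate:
#' plate identifier, well row (A-P), well column (1-24) and site (field of
#' view, 1-based). Its canonical string form is `"PLATE-RowCol-Site"` with a
#' zero-padded two-digit column, e.g. `"BR00116991-A02-5"`.
#'
#' @param plate_id Plate identifier string (alphanumeric).
#' @param well_row Well row letter, `"A"`..`"P"`.
#' @param well_col Well column, integer 1..24.
#' @param site Field-of-view index, integer >= 1.
#' @return An object of class `plate_coord`.
#' @export
plate_coord <- function(plate_id, well_row, well_col, site = 1L) {
  stopifnot(is.character(plate_id), length(plate_id) == 1L, nzchar(plate_id))
  well_row <- toupper(as.character(well_row))
  if (!well_row %in% LETTERS[1:16])
    stop("well_row must be a letter A-P, got '", well_row, "'")
  well_col <- as.integer(well_col)
  if (is.na(well_col) || well_col < 1L || well_col > 24L)
    stop("well_col must be in 1..24, got ", well_col)
  site <- as.integer(site)
  if (is.na(site) || site < 1L)
    stop("site must be a positive integer, got ", site)
  structure(
    list(plate_id = plate_id, well_row = well_row,
         well_col = well_col, site = site),
    class = "plate_coord"
  )
}

#' @export
format.plate_coord <- function(x, ...) {
  sprintf("%s-%s%02d-%d", x$plate_id, x$well_row, x$well_col, x$site)
}

#' @export
print.plate_coord <- function(x, ...) {
  cat("<plate_coord>", format(x), "\n")
  invisible(x)
}

#' Parse an image name into a plate coordinate
#'
#' Image names fuse plate, well and field-of-view identifiers as
#' `"PLATE-RowCol-Site"` (e.g. `"BR00116991-A02-5"`). Columns may be written
#' with one or two digits; the canonical form emitted by [format.plate_coord()]
#' is always zero-padded to two.
#'
#' @param name Image name string.
#' @return A [plate_coord()] object.
#' @export
#' @examples
#' parse_image_name("BR00116991-A02-5")
parse_image_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("image name is empty")
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("malformed image name '", name,
         "': expected PLATE-RowCol-Site with two '-' separators")
  well <- parts[2]
  m <- regmatches(well, regexec("^([A-Pa-p])([0-9]{1,2})$", well))[[1]]
  if (length(m) != 3L)
    stop("malformed well token '", well, "' in image name '", name, "'")
  site <- suppressWarnings(as.integer(parts[3]))
  if (is.na(site))
    stop("malformed site token '", parts[3], "' in image name '", name, "'")
  col <- as.integer(m[3])
  if (col < 1L || col > 24L)
    stop("well column out of range 1..24 in token '", well, "'")
  plate_coord(parts[1], m[2], col, site)
}

.default_channels <- c("DNA", "ER", "RNA", "AGP", "Mito", "BF1", "BF2", "BF3")

#' Multi-channel image stacks
#'
#' A channel stack is an ordered set of single-channel intensity images
#' (16-bit range, nonnegative integers) sharing dimensions, with unique channel
#' names. The default channel order follows the Cell Painting assay: DNA, ER,
#' RNA, AGP (actin/Golgi/plasma membrane), Mito, plus three brightfield planes.
#'
#' @param pixels Numeric H x W x C array (or H x W matrix for C = 1) of
#'   intensities in `[0, 65535]`.
#' @param channel_names Character vector of length C, unique.
#' @param coord Optional [plate_coord()].
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(pixels, channel_names = .default_channels, coord = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (dim(pixels)[3] != length(channel_names))
    stop("channel_names length (", length(channel_names),
         ") does not match number of planes (", dim(pixels)[3], ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 65535)
    stop("intensities must lie in [0, 65535]")
  structure(
    list(pixels = pixels, channel_names = as.character(channel_names),
         coord = coord),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<channel_stack> %d x %d px, %d channels: %s\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Extract one channel from a stack
#'
#' @param stack A [channel_stack()].
#' @param channel Channel name.
#' @return H x W numeric matrix.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "channel_stack"))
  i <- match(channel, stack$channel_names)
  if (is.na(i))
    stop("channel '", channel, "' not present in stack (have: ",
         paste(stack$channel_names, collapse = ", "), ")")
  stack$pixels[, , i]
}

#' Read a channel stack from per-channel grayscale TIFF files
#'
#' One file per channel; files must share dimensions and be 8- or 16-bit
#' grayscale. Intensities are preserved bit-exactly. Either pass a named
#' vector of paths (name = channel), or a vector of paths plus a
#' `channel_map` of regular-expression patterns, one per channel, used to
#' locate that channel's file among `paths`.
#'
#' @param paths Character vector of file paths; named by channel if
#'   `channel_map` is `NULL`.
#' @param channel_map Optional named character vector: channel name ->
#'   regex pattern matched against `basename(paths)`.
#' @param coord Optional [plate_coord()] attached to the stack.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(paths, channel_map = NULL, coord = NULL) {
  if (is.null(channel_map)) {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
      stop("paths must be named by channel when channel_map is NULL")
    files <- paths
  } else {
    files <- vapply(names(channel_map), function(ch) {
      hit <- grep(channel_map[[ch]], basename(paths))
      if (length(hit) == 0L)
        stop("missing channel file: no path matches pattern '",
             channel_map[[ch]], "' for channel '", ch, "'")
      if (length(hit) > 1L)
        stop("ambiguous channel '", ch, "': ", length(hit), " paths match")
      paths[hit]
    }, character(1))
  }
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing channel file(s): ", paste(missing, collapse = ", "))
  planes <- lapply(files, read_gray_image)
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("channel images differ in shape: ",
         paste(sprintf("%s=%dx%d", names(files), dims[1, ], dims[2, ]),
               collapse = ", "))
  px <- array(0, c(unname(dims[1, 1]), unname(dims[2, 1]), length(planes)))
  for (i in seq_along(planes)) px[, , i] <- planes[[i]]
  channel_stack(px, names(files), coord = coord)
}

# Read a single grayscale image (TIFF or PNG) as an integer-valued matrix on
# its native bit scale. Multi-sample (colour) input is rejected.
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    # png returns [0,1]; recover the integer code on an 8- or 16-bit scale
    scale <- if (max(img) <= 1 && any(abs(img * 255 - round(img * 255)) > 1e-6))
      65535 else 255
    img <- round(img * scale)
  } else {
    stop("unsupported image format '", ext, "' for ", path)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1]
    else stop("non-grayscale image (", dim(img)[3], " samples): ", path)
  }
  storage.mode(img) <- "double"
  img
}

#' Write a label mask or intensity image as 16-bit grayscale
#'
#' @param x Integer-valued matrix (labels or intensities, max 65535).
#' @param path Output path; extension selects TIFF or PNG.
#' @export
write_mask <- function(x, path) {
  stopifnot(is.matrix(x), max(x) <= 65535, min(x) >= 0)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(x / 65535, path)
  } else stop("unsupported output format '", ext, "'")
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path File path.
#' @return Integer matrix.
#' @export
read_mask <- function(path) {
  m <- read_gray_image(path)
  # 16-bit PNG comes back on the 255 scale heuristically only when integral;
  # write_mask always writes 16-bit, so rescale PNG reads accordingly.
  if (tolower(tools::file_ext(path)) == "png") {
    raw <- png::readPNG(path)
    m <- round(raw * 65535)
    if (length(dim(m)) == 3L) m <- m[, , 1]
  }
  storage.mode(m) <- "integer"
  m
}

.key_cols <- c("plate", "well", "site", "compartment", "object_id")

#' Construct a per-object feature table
#'
#' Rows are objects identified by (plate, well, site, compartment, object_id);
#' remaining columns are numeric feature values in the deterministic order of
#' the catalog that produced them.
#'
#' @param keys Data frame with columns plate, well, site, compartment,
#'   object_id.
#' @param values Numeric matrix or data frame of feature values, one row per
#'   object.
#' @return A data frame of class `feature_table`.
#' @export
feature_table <- function(keys, values) {
  stopifnot(all(.key_cols %in% names(keys)))
  values <- as.data.frame(values, optional = TRUE)
  if (nrow(keys) != nrow(values) && nrow(keys) > 0)
    stop("keys and values disagree in row count")
  out <- cbind(keys[.key_cols], values)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature column names of a feature table
#' @param table A feature table.
#' @return Character vector of non-key columns.
#' @export
feature_columns <- function(table) setdiff(names(table), .key_cols)

#' Write a feature table to CSV
#'
#' Columns are `plate,well,site,compartment,object_id` followed by the feature
#' columns. Values round-trip through [read_feature_table()] to within 1e-12
#' relative error (15 significant digits are written).
#'
#' @param table Feature table.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  for (cn in feature_columns(table))
    df[[cn]] <- formatC(df[[cn]], digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path as written by [write_feature_table()].
#' @return A feature table; non-numeric feature cells raise an error naming
#'   the row and column.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(.key_cols %in% names(df)))
    stop("malformed feature CSV: missing key column(s) ",
         paste(setdiff(.key_cols, names(df)), collapse = ", "))
  for (cn in c("site", "object_id")) df[[cn]] <- as.integer(df[[cn]])
  for (cn in setdiff(names(df), .key_cols)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
    if (length(bad))
      stop("non-numeric cell in feature CSV: row ", bad[1],
           ", column '", cn, "' (value '", df[[cn]][bad[1]], "')")
    df[[cn]] <- v
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

.default_categories <- c(hit = 28L, diverse_nonhit = 19L,
                         positive_control = 10L, negative_control = 64L)

#' Build a subset-selection manifest
#'
#' Reproduces the study-design selection: the same well positions on every
#' plate, partitioned into hit, diverse non-hit, positive-control and
#' negative-control categories (defaults 28/19/10/64 = 121 wells), imaged at a
#' single site (default 5, the central field of a 3 x 3 grid). Wells are
#' assigned in plate raster order (A01, A02, ..., B01, ...), category by
#' category.
#'
#' @param plate_ids Character vector of plate identifiers.
#' @param wells_per_category Named integer vector of category sizes.
#' @param site Field-of-view index used for every entry.
#' @return Data frame with columns plate, well_row, well_col, site, category
#'   and the canonical image name; one row per (plate, well).
#' @export
build_subset_manifest <- function(plate_ids,
                                  wells_per_category = .default_categories,
                                  site = 5L) {
  total <- sum(wells_per_category)
  if (total > 16L * 24L)
    stop("category counts (", total, ") exceed the 384-well plate capacity")
  if (any(wells_per_category < 0L)) stop("negative category count")
  rows <- rep(LETTERS[1:16], each = 24L)
  cols <- rep(1:24, times = 16L)
  category <- rep(names(wells_per_category), times = wells_per_category)
  idx <- seq_len(total)
  if (length(plate_ids) == 0L) {
    out <- data.frame(plate = character(), well_row = character(),
                      well_col = integer(), site = integer(),
                      category = character(), image = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, lapply(plate_ids, function(p) {
    data.frame(plate = p, well_row = rows[idx], well_col = cols[idx],
               site = as.integer(site), category = category,
               stringsAsFactors = FALSE)
  }))
  out$image <- sprintf("%s-%s%02d-%d", out$plate, out$well_row,
                       out$well_col, out$site)
  if (anyDuplicated(out[c("plate", "well_row", "well_col", "site")]))
    stop("duplicate well assignment in manifest")
  rownames(out) <- NULL
  out
}

#' Write / read a manifest CSV
#' @param manifest Manifest data frame from [build_subset_manifest()].
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
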