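# Feature-table quality control and correlation-based prioritization.

#' Compare a measured feature table against a reference
#'
#' Tables are aligned by (plate, well, site, compartment, object_id); both
#' columns of each feature are min-max normalized with the *reference*
#' column's min and max (a zero-range reference feature contributes residual
#' 0 where the tables agree and 1 where they differ). Mean squared error and
#' mean absolute error are then pooled over all objects x features within
#' each feature group, plus an overall row pooling every compared cell.
#' Identical tables yield all zeros, and `mae^2 <= mse` per group.
#'
#' @param measured,reference Feature tables sharing keys and feature columns.
#' @param grouping Optional named character vector mapping feature column ->
#'   group label; defaults to the text before the first underscore of each
#'   column name.
#' @param bounds `"reference"` (default) anchors the min-max normalization on
#'   the reference column; `"pooled"` uses the min/max over both tables,
#'   which makes the comparison symmetric under swapping the two tables.
#' @return Data frame of class `qc_report` with columns group, n_features,
#'   mse, mae; the last row is `Overall`.
#' @export
compare_feature_tables <- function(measured, reference, grouping = NULL,
                                   bounds = c("reference", "pooled")) {
  bounds <- match.arg(bounds)
  fc_m <- feature_columns(measured); fc_r <- feature_columns(reference)
  if (!setequal(fc_m, fc_r))
    stop("feature column mismatch: only in measured: ",
         paste(setdiff(fc_m, fc_r), collapse = ", "),
         "; only in reference: ",
         paste(setdiff(fc_r, fc_m), collapse = ", "))
  key_m <- do.call(paste, c(measured[.key_cols], sep = "\r"))
  key_r <- do.call(paste, c(reference[.key_cols], sep = "\r"))
  if (anyDuplicated(key_m) || anyDuplicated(key_r))
    stop("duplicate object keys in feature table")
  if (!setequal(key_m, key_r)) {
    miss <- c(setdiff(key_m, key_r), setdiff(key_r, key_m))
    stop("object keys do not match between tables: ",
         paste(gsub("\r", "/", utils::head(miss, 5)), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  }
  measured <- measured[order(key_m), , drop = FALSE]
  reference <- reference[order(key_r), , drop = FALSE]
  cols <- fc_r
  if (is.null(grouping))
    grouping <- stats::setNames(feature_groups_of(cols), cols)
  resid <- matrix(NA_real_, nrow(reference), length(cols),
                  dimnames = list(NULL, cols))
  for (cn in cols) {
    y <- reference[[cn]]; yh <- measured[[cn]]
    if (bounds == "pooled") { lo <- min(y, yh); hi <- max(y, yh) }
    else { lo <- min(y); hi <- max(y) }
    if (hi > lo) {
      resid[, cn] <- (y - lo) / (hi - lo) - (yh - lo) / (hi - lo)
    } else {
      resid[, cn] <- ifelse(yh == y, 0, 1)
    }
  }
  groups <- sort(unique(grouping[cols]))
  rows <- lapply(groups, function(g) {
    r <- as.vector(resid[, cols[grouping[cols] == g], drop = FALSE])
    data.frame(group = g, n_features = sum(grouping[cols] == g),
               mse = mean(r^2), mae = mean(abs(r)))
  })
  all_r <- as.vector(resid)
  out <- rbind(do.call(rbind, rows),
               data.frame(group = "Overall", n_features = length(cols),
                          mse = mean(all_r^2), mae = mean(abs(all_r))))
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Write a QC report as CSV
#' @param report A `qc_report`.
#' @param path Output CSV path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Correlation-based feature prioritization
#'
#' Redundancy reduction: features are scanned in descending variance order
#' (ties broken by catalog/column order); a feature is retained iff its
#' absolute Pearson correlation with every already-retained feature is below
#' `corr_threshold`. Zero-variance features are always dropped. The result
#' is invariant to the order of the object rows.
#'
#' @param table Feature table with at least 2 objects.
#' @param corr_threshold Threshold in (0, 1] (default 0.9).
#' @return Character vector of retained feature identifiers, in scan order.
#' @export
prioritize_features <- function(table, corr_threshold = 0.9) {
  if (corr_threshold <= 0 || corr_threshold > 1)
    stop("corr_threshold must lie in (0, 1]")
  cols <- feature_columns(table)
  X <- as.matrix(table[cols])
  if (nrow(X) < 2L) stop("prioritization needs at least 2 objects")
  v <- apply(X, 2, stats::var)
  cols <- cols[v > 0]
  if (!length(cols)) return(character(0))
  v <- v[cols]
  ord <- cols[order(-v, seq_along(cols))]
  kept <- character(0)
  for (cn in ord) {
    if (!length(kept)) { kept <- cn; next }
    r <- abs(stats::cor(X[, cn], X[, kept, drop = FALSE]))
    if (all(r < corr_threshold)) kept <- c(kept, cn)
  }
  kept
}
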