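# Instance matching and object-level detection metrics.

#' Match predicted instances against ground truth by IoU
#'
#' Candidate pairs are all (ground truth, prediction) label pairs with
#' nonzero pixel overlap; each pair's IoU is the ratio of intersection to
#' union pixel counts. Pairs with IoU at or above the threshold are accepted
#' greedily in descending IoU (ties broken by lower ground-truth label, then
#' lower prediction label), one-to-one. Unmatched predictions are false
#' positives, unmatched ground-truth objects false negatives. With internally
#' disjoint instance masks and a threshold of at least 0.5, a prediction can
#' overlap at most one ground-truth object above threshold, so greedy
#' matching is optimal.
#'
#' @param gt,pred Integer label masks of equal dimensions.
#' @param iou_threshold Matching threshold in (0, 1]; matches require
#'   IoU >= threshold (default 0.5).
#' @return Object of class `match_result`: list with `pairs` (data frame of
#'   gt, pred, iou), `tp`, `fp`, `fn`, `iou_threshold`.
#' @export
match_instances <- function(gt, pred, iou_threshold = 0.5) {
  gt <- as_label_matrix(gt); pred <- as_label_matrix(pred)
  check_same_dim(gt, pred, "gt and pred")
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  gt_areas <- label_areas(gt)
  pr_areas <- label_areas(pred)
  sel <- gt > 0L & pred > 0L
  if (any(sel)) {
    ov <- table(gt = gt[sel], pred = pred[sel])
    cand <- as.data.frame(ov, stringsAsFactors = FALSE)
    cand <- cand[cand$Freq > 0L, ]
    cand$gt <- as.integer(cand$gt); cand$pred <- as.integer(cand$pred)
    inter <- cand$Freq
    uni <- gt_areas[as.character(cand$gt)] +
      pr_areas[as.character(cand$pred)] - inter
    cand$iou <- as.numeric(inter / uni)
  } else {
    cand <- data.frame(gt = integer(0), pred = integer(0),
                       Freq = integer(0), iou = numeric(0))
  }
  cand <- cand[cand$iou >= iou_threshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$gt, cand$pred), , drop = FALSE]
  used_gt <- integer(0); used_pred <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$gt[i] %in% used_gt || cand$pred[i] %in% used_pred) next
    keep[i] <- TRUE
    used_gt <- c(used_gt, cand$gt[i])
    used_pred <- c(used_pred, cand$pred[i])
  }
  pairs <- cand[keep, c("gt", "pred", "iou"), drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 tp = nrow(pairs),
                 fp = length(pr_areas) - nrow(pairs),
                 fn = length(gt_areas) - nrow(pairs),
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp=%d fp=%d fn=%d @ IoU>=%.2f\n",
              x$tp, x$fp, x$fn, x$iou_threshold))
  invisible(x)
}

#' Object-level detection metrics from matched counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 `2PR/(P+R)` (0 when
#' P + R = 0), average precision in the detection-Jaccard sense
#' `AP = TP/(TP+FP+FN)`, and the mean IoU over matched pairs (0 with no
#' pairs). For all count triples, `AP <= min(P, R)` and `F1 >= AP`.
#'
#' @param match A `match_result`, or a list/vector with elements `tp`, `fp`,
#'   `fn` (and optionally `pairs`).
#' @return Object of class `detection_metrics`: list with precision, recall,
#'   f1, ap, mean_matched_iou and the counts.
#' @export
detection_metrics <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (tp + fp + fn <= 0) stop("no objects: tp + fp + fn must be positive")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  ap <- tp / (tp + fp + fn)
  miou <- if (!is.null(match$pairs) && nrow(match$pairs))
    mean(match$pairs$iou) else 0
  structure(list(precision = p, recall = r, f1 = f1, ap = ap,
                 mean_matched_iou = miou,
                 tp = tp, fp = fp, fn = fn),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics> P=%.4f R=%.4f F1=%.4f AP=%.4f meanIoU=%.4f (tp=%d fp=%d fn=%d)\n",
    x$precision, x$recall, x$f1, x$ap, x$mean_matched_iou, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Pixelwise foreground IoU between two masks
#'
#' Jaccard index of the binarized foregrounds, the semantic-segmentation
#' companion to the object-level metrics.
#'
#' @param gt,pred Integer label masks.
#' @return IoU in `[0, 1]` (1 when both masks are empty).
#' @export
pixel_iou <- function(gt, pred) {
  check_same_dim(gt, pred, "gt and pred")
  a <- gt > 0L; b <- pred > 0L
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Invert printed precision/recall/false-positive counts into raw counts
#'
#' Given a printed precision and recall (as percentages) and a false-positive
#' count, recovers TP and FN by inverting the precision and recall formulas:
#' `TP = FP * P / (1 - P)` and `FN = TP * (1 - R) / R`.
#'
#' @param precision_pct,recall_pct Precision and recall in percent.
#' @param false_positives False-positive count.
#' @return Named list with tp, fp, fn (tp and fn rounded to whole objects).
#' @export
counts_from_precision_recall <- function(precision_pct, recall_pct,
                                         false_positives) {
  p <- precision_pct / 100; r <- recall_pct / 100
  stopifnot(p > 0, p < 1, r > 0, r <= 1)
  tp <- false_positives * p / (1 - p)
  fn <- tp * (1 - r) / r
  list(tp = round(tp), fp = false_positives, fn = round(fn))
}

#' Evaluation report for a set of images
#'
#' Aggregates per-image match results into pooled counts and metrics plus a
#' per-image breakdown, in the JSON-ready list layout used by the pipeline.
#'
#' @param matches Named list of `match_result` objects (one per image).
#' @param pixel_ious Optional named numeric vector of pixelwise foreground
#'   IoUs per image.
#' @return List with counts, metrics and per_image entries.
#' @export
evaluation_report <- function(matches, pixel_ious = NULL) {
  tp <- sum(vapply(matches, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(matches, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(matches, `[[`, numeric(1), "fn"))
  all_ious <- unlist(lapply(matches, function(m) m$pairs$iou))
  pooled <- detection_metrics(list(tp = tp, fp = fp, fn = fn,
                                   pairs = data.frame(iou = all_ious)))
  per_image <- lapply(names(matches), function(nm) {
    m <- matches[[nm]]
    dm <- detection_metrics(m)
    out <- list(image = nm, tp = m$tp, fp = m$fp, fn = m$fn,
                precision = dm$precision, recall = dm$recall, f1 = dm$f1,
                ap = dm$ap, mean_matched_iou = dm$mean_matched_iou)
    if (!is.null(pixel_ious) && nm %in% names(pixel_ious))
      out$pixel_iou <- unname(pixel_ious[[nm]])
    out
  })
  list(counts = list(tp = tp, fp = fp, fn = fn),
       precision = pooled$precision, recall = pooled$recall,
       f1 = pooled$f1, ap = pooled$ap,
       mean_matched_iou = pooled$mean_matched_iou,
       mean_pixel_iou = if (!is.null(pixel_ious)) mean(pixel_ious) else NULL,
       per_image = per_image)
}
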