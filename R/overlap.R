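# Overlap module: TP/FP/TN/FN pixel classification within a region of
# interest and the seven derived overlap metrics.

#' Region of interest from the vessel markers
#'
#' Bounding box of all vessel marker endpoints (proximal border, lesion,
#' distal border), padded and clipped to the canvas. Returned half-open:
#' rows \code{[row_min, row_max)}, cols \code{[col_min, col_max)}, 0-based.
#'
#' @param ref a \linkS4class{QcaReference} with at least one vessel marker.
#' @param canvas integer(2) canvas size (rows, cols) used for clipping.
#' @param padding padding in pixels added on every side (default 10).
#' @return list of class \code{Roi} with \code{row_min}, \code{row_max},
#'   \code{col_min}, \code{col_max}.
#' @export
roiFromMarkers <- function(ref, canvas, padding = 10) {
  stopifnot(is(ref, "QcaReference"))
  mk <- ref@markers[ref@markers$role %in% .VESSEL_ROLES, ]
  if (!nrow(mk)) .stopf("at least one vessel marker is required")
  rows <- c(mk$r0, mk$r1); cols <- c(mk$c0, mk$c1)
  roi <- list(row_min = max(0L, floor(min(rows) - padding)),
              row_max = min(canvas[1], ceiling(max(rows) + padding) + 1),
              col_min = max(0L, floor(min(cols) - padding)),
              col_max = min(canvas[2], ceiling(max(cols) + padding) + 1))
  roi <- lapply(roi, as.integer)
  if (roi$row_max <= roi$row_min || roi$col_max <= roi$col_min)
    .stopf("ROI is empty")
  structure(roi, class = "Roi")
}

#' Classify pixels into TP/FP/TN/FN
#'
#' Per-pixel comparison of a reference mask (the "original image" role) and
#' a predicted mask, restricted to a region of interest. TP: in-class in
#' both; FP: in-class only in the prediction; TN: out-of-class in both;
#' FN: in-class only in the reference.
#'
#' @param reference_mask,predicted_mask \linkS4class{SegmentationMask}s of
#'   identical shape and spacing.
#' @param roi a \code{Roi} from \code{\link{roiFromMarkers}}, or NULL for
#'   the whole image.
#' @param class_label class to score (default 1, coronary).
#' @return An \linkS4class{OverlapCounts}.
#' @export
classifyPixels <- function(reference_mask, predicted_mask, roi = NULL,
                           class_label = 1L) {
  stopifnot(is(reference_mask, "SegmentationMask"),
            is(predicted_mask, "SegmentationMask"))
  if (!identical(dim(reference_mask@labels), dim(predicted_mask@labels)))
    .stopf("invalid-input: masks must share shape")
  a <- reference_mask@labels
  b <- predicted_mask@labels
  if (!is.null(roi)) {
    rr <- (roi$row_min + 1L):roi$row_max
    cc <- (roi$col_min + 1L):roi$col_max
    if (any(rr < 1L) || any(rr > nrow(a)) || any(cc < 1L) ||
        any(cc > ncol(a)))
      .stopf("invalid-input: ROI exceeds the canvas")
    a <- a[rr, cc, drop = FALSE]
    b <- b[rr, cc, drop = FALSE]
  }
  ra <- a == class_label
  rb <- b == class_label
  OverlapCounts(tp = sum(ra & rb), fp = sum(!ra & rb),
                tn = sum(!ra & !rb), fn = sum(ra & !rb))
}

#' The seven overlap metrics from confusion counts
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN), IoU TP/(TP+FN+FP) and
#' Dice 2TP/(2TP+FN+FP). A metric with a zero denominator is undefined and
#' reported as NA with a warning -- never as 0.
#'
#' @param counts an \linkS4class{OverlapCounts}.
#' @return An \linkS4class{OverlapMetrics} (fractions; percentages via
#'   \code{as.data.frame} or \code{show}).
#' @examples
#' m <- overlapMetrics(OverlapCounts(90, 5, 900, 5))
#' as.data.frame(m)$dice  # 94.74
#' @export
overlapMetrics <- function(counts) {
  stopifnot(is(counts, "OverlapCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  if (tp + fp + tn + fn == 0)
    .stopf("all overlap counts are zero")
  frac <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s is undefined (zero denominator)", name),
              call. = FALSE)
      NA_real_
    } else num / den
  }
  new("OverlapMetrics",
      accuracy = frac(tp + tn, tp + tn + fp + fn, "accuracy"),
      sensitivity = frac(tp, tp + fn, "sensitivity"),
      specificity = frac(tn, tn + fp, "specificity"),
      ppv = frac(tp, tp + fp, "PPV"),
      npv = frac(tn, tn + fn, "NPV"),
      iou = frac(tp, tp + fn + fp, "IoU"),
      dice = frac(2 * tp, 2 * tp + fn + fp, "Dice"),
      counts = counts)
}

#' Dice score implied by an IoU (Jaccard) value
#'
#' The two overlap measures are algebraically linked:
#' \eqn{D = 2J / (1 + J)}.
#'
#' @param iou IoU as a fraction in \[0, 1\].
#' @return The implied Dice fraction.
#' @examples
#' diceFromIoU(0.901)  # 0.9479...
#' @export
diceFromIoU <- function(iou) {
  if (any(iou < 0 | iou > 1, na.rm = TRUE))
    .stopf("iou must lie in [0, 1]")
  2 * iou / (1 + iou)
}
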