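#' @include AllClasses.R
NULL

#' Accessors for phantomQCA objects
#'
#' @param x an object of the class the accessor documents.
#' @return The slot value: a label matrix (\code{maskLabels}), mm/pixel
#'   spacing (\code{pixelSpacing}), masks (\code{truthMask},
#'   \code{predictedMask}), a \linkS4class{QcaReference}
#'   (\code{qcaReference}), the analytic truth record (\code{truthRecord}),
#'   marker line table (\code{markerLines}), reference diameter in mm
#'   (\code{referenceDiameter}), calibration (\code{calibration}), the
#'   per-case table of a study (\code{casesTable}) or its manifest
#'   (\code{studyManifest}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))
#' @rdname accessors
#' @export
setGeneric("predictedMask", function(x) standardGeneric("predictedMask"))
#' @rdname accessors
#' @export
setGeneric("qcaReference", function(x) standardGeneric("qcaReference"))
#' @rdname accessors
#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))
#' @rdname accessors
#' @export
setGeneric("markerLines", function(x) standardGeneric("markerLines"))
#' @rdname accessors
#' @export
setGeneric("referenceDiameter", function(x) standardGeneric("referenceDiameter"))
#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setGeneric("casesTable", function(x) standardGeneric("casesTable"))
#' @rdname accessors
#' @export
setGeneric("studyManifest", function(x) standardGeneric("studyManifest"))
#' @rdname accessors
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))

#' @rdname accessors
setMethod("maskLabels", "SegmentationMask", function(x) x@labels)
#' @rdname accessors
setMethod("pixelSpacing", "SegmentationMask", function(x) x@spacing)
#' @rdname accessors
setMethod("truthMask", "PhantomCase", function(x) x@truth)
#' @rdname accessors
setMethod("predictedMask", "PhantomCase", function(x) x@predicted)
#' @rdname accessors
setMethod("qcaReference", "PhantomCase", function(x) x@reference)
#' @rdname accessors
setMethod("truthRecord", "PhantomCase", function(x) x@truthRecord)
#' @rdname accessors
setMethod("markerLines", "QcaReference", function(x) x@markers)
#' @rdname accessors
setMethod("referenceDiameter", "QcaReference", function(x) x@referenceDiameter)
#' @rdname accessors
setMethod("calibration", "QcaReference", function(x) x@calibration)
#' @rdname accessors
setMethod("casesTable", "StudyResult", function(x) x@cases)
#' @rdname accessors
setMethod("studyManifest", "StudyResult", function(x) x@manifest)
#' @rdname accessors
setMethod("overlapCounts", "OverlapMetrics", function(x) x@counts)

#' @describeIn SegmentationMask-class dimensions of the label grid
#' @param x a SegmentationMask
#' @export
setMethod("dim", "SegmentationMask", function(x) dim(x@labels))

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@labels)
  tab <- tabulate(object@labels + 1L, nbins = 3L)
  cat(sprintf("SegmentationMask %dx%d px @ %.4g mm/px\n", d[1], d[2],
              object@spacing))
  cat(sprintf("  background: %d  coronary: %d  catheter: %d\n",
              tab[1], tab[2], tab[3]))
})

setMethod("show", "QcaReference", function(object) {
  cat(sprintf("QcaReference: %d marker line(s); reference diameter %.3f mm; calibration %.4g mm/px",
              nrow(object@markers), object@referenceDiameter,
              object@calibration))
  if (!is.na(object@catheterFrench))
    cat(sprintf("; catheter %d Fr", object@catheterFrench))
  cat("\n  roles:", paste(object@markers$role, collapse = ", "), "\n")
})

setMethod("show", "PhantomCase", function(object) {
  tr <- object@truthRecord
  cat(sprintf("PhantomCase %dx%d px @ %.4g mm/px (seed %s)\n",
              nrow(object@truth@labels), ncol(object@truth@labels),
              object@truth@spacing,
              as.character(object@provenance$seed)))
  cat(sprintf("  truth: reference %.3f mm, lesion %.3f mm, stenosis %.1f%%\n",
              tr[["reference_mm"]], tr[["lesion_mm"]],
              tr[["stenosis_percent"]]))
  w <- object@provenance$warnings
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
})

setMethod("show", "OverlapCounts", function(object) {
  cat(sprintf("OverlapCounts: TP %d  FP %d  TN %d  FN %d (n = %d)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

setMethod("show", "OverlapMetrics", function(object) {
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.2f%%", 100 * v))
  cat("OverlapMetrics (coronary class):\n")
  cat(sprintf("  accuracy %s  sensitivity %s  specificity %s\n",
              fmt(object@accuracy), fmt(object@sensitivity),
              fmt(object@specificity)))
  cat(sprintf("  PPV %s  NPV %s  IoU %s  Dice %s\n",
              fmt(object@ppv), fmt(object@npv), fmt(object@iou),
              fmt(object@dice)))
})

setMethod("show", "StudyResult", function(object) {
  m <- object@manifest
  cat(sprintf("StudyResult: %d generated, %d included, %d excluded (seed %s)\n",
              m$n_generated, m$n_included, m$n_excluded,
              as.character(m$seed)))
  if (nrow(object@overlapSummary))
    cat(sprintf("  median Dice (ROI): %.1f%%\n",
                object@overlapSummary$median[object@overlapSummary$metric == "dice"]))
})

#' Coerce OverlapMetrics to a one-row data.frame of percentages
#'
#' @param x an \linkS4class{OverlapMetrics}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return one-row data.frame with the seven metrics in percent plus the raw
#'   counts.
#' @export
as.data.frame.OverlapMetrics <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(accuracy = 100 * x@accuracy, sensitivity = 100 * x@sensitivity,
             specificity = 100 * x@specificity, ppv = 100 * x@ppv,
             npv = 100 * x@npv, iou = 100 * x@iou, dice = 100 * x@dice,
             tp = x@counts@tp, fp = x@counts@fp, tn = x@counts@tn,
             fn = x@counts@fn)
}
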