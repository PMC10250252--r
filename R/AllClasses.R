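#' @import methods
NULL

#' Label encoding for segmentation masks
#'
#' Masks use integer labels 0 = background, 1 = coronary tree, 2 = catheter.
#' On disk (8-bit grayscale PNG) these map to 0, 255 and 128 respectively,
#' which is lossless and diff-friendly.
#'
#' @name maskEncoding
#' @keywords internal
NULL

.MASK_LEVELS <- c(background = 0L, coronary = 1L, catheter = 2L)

#' SegmentationMask: a 2-D label grid with pixel spacing
#'
#' The unit every stage of the pipeline consumes: a matrix of class labels
#' (0 background, 1 coronary, 2 catheter) with an isotropic pixel spacing in
#' mm/pixel. Pixel coordinates are 0-based \code{(row, col)} with pixel
#' centres at integer coordinates.
#'
#' @slot labels integer matrix of labels in \{0, 1, 2\}.
#' @slot spacing numeric(1), mm per pixel (isotropic).
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(labels = "matrix", spacing = "numeric"))

setValidity("SegmentationMask", function(object) {
  msg <- character()
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "pixel spacing must be a single positive number")
  lab <- object@labels
  if (!is.numeric(lab) || any(!(lab %in% 0:2)))
    msg <- c(msg, "labels must all be 0 (background), 1 (coronary) or 2 (catheter)")
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentationMask
#'
#' @param labels integer matrix with values in \{0, 1, 2\}.
#' @param spacing pixel spacing in mm/pixel (isotropic).
#' @return A \linkS4class{SegmentationMask}.
#' @examples
#' m <- SegmentationMask(matrix(0L, 32, 32), spacing = 0.1)
#' @export
SegmentationMask <- function(labels, spacing) {
  storage.mode(labels) <- "integer"
  new("SegmentationMask", labels = labels, spacing = as.numeric(spacing))
}

#' QcaReference: a CAAS-style measurement reference for one case
#'
#' Holds the marker line segments (proximal border, lesion, distal border and
#' optionally two catheter caliper lines), the interpolated healthy reference
#' diameter at the lesion, the image calibration, and the catheter French
#' size. Marker endpoints are continuous 0-based (row, col) pixel coordinates.
#'
#' @slot markers data.frame with columns \code{role}, \code{r0}, \code{c0},
#'   \code{r1}, \code{c1}; one row per marker line.
#' @slot referenceDiameter numeric(1), reference (healthy) diameter in mm.
#' @slot calibration numeric(1), mm per pixel.
#' @slot catheterFrench integer(1), 5 or 6, or NA when absent.
#' @exportClass QcaReference
setClass("QcaReference",
  representation(markers = "data.frame", referenceDiameter = "numeric",
                 calibration = "numeric", catheterFrench = "integer"))

.VESSEL_ROLES <- c("proximal_border", "lesion", "distal_border")
.CATH_ROLES <- c("catheter_caliper_a", "catheter_caliper_b")

setValidity("QcaReference", function(object) {
  msg <- character()
  mk <- object@markers
  need <- c("role", "r0", "c0", "r1", "c1")
  if (!all(need %in% names(mk)))
    msg <- c(msg, "markers must have columns role, r0, c0, r1, c1")
  else {
    if (anyDuplicated(mk$role))
      msg <- c(msg, "exactly one marker per role is allowed")
    bad <- !(mk$role %in% c(.VESSEL_ROLES, .CATH_ROLES))
    if (any(bad))
      msg <- c(msg, paste("unknown marker role:", paste(mk$role[bad], collapse = ", ")))
    if (any(mk$r0 == mk$r1 & mk$c0 == mk$c1))
      msg <- c(msg, "marker endpoints must differ")
  }
  if (!(length(object@referenceDiameter) == 1L && object@referenceDiameter > 0))
    msg <- c(msg, "referenceDiameter must be a single positive number")
  if (!(length(object@calibration) == 1L && object@calibration > 0))
    msg <- c(msg, "calibration must be a single positive number")
  if (!is.na(object@catheterFrench) && !(object@catheterFrench %in% c(5L, 6L)))
    msg <- c(msg, "catheterFrench must be 5, 6 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a QcaReference
#'
#' @param markers data.frame with columns \code{role}, \code{r0}, \code{c0},
#'   \code{r1}, \code{c1} (continuous 0-based pixel coordinates). Roles:
#'   \code{proximal_border}, \code{lesion}, \code{distal_border},
#'   \code{catheter_caliper_a}, \code{catheter_caliper_b}.
#' @param reference_diameter healthy reference diameter at the lesion, mm.
#' @param calibration mm per pixel.
#' @param catheter_french catheter size in French (5 or 6), or NA.
#' @return A \linkS4class{QcaReference}.
#' @export
QcaReference <- function(markers, reference_diameter, calibration,
                         catheter_french = NA_integer_) {
  markers$role <- as.character(markers$role)
  new("QcaReference", markers = markers,
      referenceDiameter = as.numeric(reference_diameter),
      calibration = as.numeric(calibration),
      catheterFrench = as.integer(catheter_french))
}

#' PhantomCase: one synthetic truth/prediction pair with analytic ground truth
#'
#' @slot truth the ground-truth \linkS4class{SegmentationMask}.
#' @slot predicted the degraded "model prediction" mask.
#' @slot reference the \linkS4class{QcaReference} for the case.
#' @slot truthRecord named numeric: \code{proximal_mm}, \code{lesion_mm},
#'   \code{distal_mm}, \code{reference_mm}, \code{stenosis_percent}, all
#'   computed analytically from the vessel geometry (never from pixels).
#' @slot geometry internal list of dense centerlines and diameter profiles.
#' @slot provenance list holding the generating specs, seed and warnings.
#' @exportClass PhantomCase
setClass("PhantomCase",
  representation(truth = "SegmentationMask", predicted = "SegmentationMask",
                 reference = "QcaReference", truthRecord = "numeric",
                 geometry = "list", provenance = "list"))

setValidity("PhantomCase", function(object) {
  msg <- character()
  if (!identical(dim(object@truth@labels), dim(object@predicted@labels)))
    msg <- c(msg, "truth and predicted masks must share shape")
  if (object@truth@spacing != object@predicted@spacing)
    msg <- c(msg, "truth and predicted masks must share pixel spacing")
  tr <- object@truthRecord
  need <- c("proximal_mm", "lesion_mm", "distal_mm", "reference_mm",
            "stenosis_percent")
  if (!all(need %in% names(tr)))
    msg <- c(msg, "truthRecord must contain proximal/lesion/distal/reference/stenosis fields")
  else {
    implied <- (tr[["reference_mm"]] - tr[["lesion_mm"]]) /
      tr[["reference_mm"]] * 100
    if (abs(implied - tr[["stenosis_percent"]]) > 1e-9)
      msg <- c(msg, "truth stenosis must equal ((reference - lesion)/reference)*100")
  }
  if (length(msg)) msg else TRUE
})

#' OverlapCounts: TP/FP/TN/FN pixel counts within a region of interest
#'
#' Pixel classification follows the standard confusion-count definitions:
#' TP = coronary in both masks, FP = coronary only in the predicted mask,
#' TN = background in both, FN = coronary only in the reference mask.
#'
#' @slot tp,fp,tn,fn non-negative pixel counts.
#' @exportClass OverlapCounts
setClass("OverlapCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"))

setValidity("OverlapCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0) ||
      any(v != round(v)))
    "tp, fp, tn, fn must be single non-negative integers" else TRUE
})

#' Construct OverlapCounts
#' @param tp,fp,tn,fn non-negative integer pixel counts.
#' @export
OverlapCounts <- function(tp, fp, tn, fn)
  new("OverlapCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn))

#' OverlapMetrics: the seven pixel-overlap metrics
#'
#' All metrics are stored as fractions in \[0, 1\]; \code{show} and
#' \code{as.data.frame} report percentages. A metric whose denominator is
#' zero is undefined and stored as NA (never as 0).
#'
#' @slot accuracy,sensitivity,specificity,ppv,npv,iou,dice fractions or NA.
#' @slot counts the \linkS4class{OverlapCounts} the metrics derive from.
#' @exportClass OverlapMetrics
setClass("OverlapMetrics",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", ppv = "numeric", npv = "numeric",
                 iou = "numeric", dice = "numeric", counts = "OverlapCounts"))

setValidity("OverlapMetrics", function(object) {
  msg <- character()
  vals <- c(object@accuracy, object@sensitivity, object@specificity,
            object@ppv, object@npv, object@iou, object@dice)
  ok <- is.na(vals) | (vals >= 0 & vals <= 1)
  if (!all(ok)) msg <- c(msg, "metrics must be fractions in [0, 1] or NA")
  if (!is.na(object@iou) && !is.na(object@dice)) {
    if (abs(object@dice - 2 * object@iou / (1 + object@iou)) > 1e-12)
      msg <- c(msg, "dice must equal 2*iou/(1+iou)")
    if (object@iou > object@dice + 1e-12)
      msg <- c(msg, "iou cannot exceed dice")
  }
  if (length(msg)) msg else TRUE
})

#' StudyResult: output of a full synthetic validation study
#'
#' @slot cases per-case data.frame: truth record, caliper measurements on
#'   both masks, overlap counts/metrics, exclusion flags and reasons.
#' @slot comparisons list of paired/grouped statistical comparisons.
#' @slot overlapSummary data.frame of median (IQR) overlap metrics.
#' @slot manifest reproducibility manifest (config hash, seeds, counts).
#' @slot config the StudyConfig the study was run with.
#' @exportClass StudyResult
setClass("StudyResult",
  representation(cases = "data.frame", comparisons = "list",
                 overlapSummary = "data.frame", manifest = "list",
                 config = "list"))

setValidity("StudyResult", function(object) {
  m <- object@manifest
  need <- c("n_generated", "n_included", "n_excluded")
  if (!all(need %in% names(m)))
    return("manifest must carry n_generated, n_included, n_excluded")
  if (m$n_included + m$n_excluded != m$n_generated)
    return("flowchart reconciliation failed: included + excluded != generated")
  TRUE
})
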