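# Caliper module: diameter measurement on segmentation masks along QCA
# marker lines, calibration to millimetres, and percent diameter stenosis.

#' Chord length of a class along a marker line
#'
#' Samples the segment \code{p0 -> p1} every \code{step} pixels; a sample is
#' in-class when its nearest pixel carries \code{class_label}. The chord is
#' the contiguous in-class run containing the sample nearest the segment
#' midpoint. If the midpoint sample is out-of-class, the nearest in-class
#' run within \code{tolerance} pixels of the midpoint is used (off-centre
#' marker tolerance); failing that, a gap is signalled by returning
#' \code{NA}. Summing disjoint runs would overestimate diameters across
#' segmentation gaps, so gaps are made explicit instead.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param p0,p1 numeric(2) endpoints, 0-based (row, col), inside the canvas.
#' @param class_label label to measure (default 1, coronary).
#' @param step sampling step along the line in pixels (default 0.1).
#' @param tolerance off-centre search radius in pixels (default 2).
#' @return Chord length in pixels, or \code{NA} (gap signal).
#' @export
chordLength <- function(mask, p0, p1, class_label = 1L, step = 0.1,
                        tolerance = 2) {
  stopifnot(is(mask, "SegmentationMask"))
  if (step <= 0) .stopf("sampling step must be > 0")
  lab <- mask@labels
  nr <- nrow(lab); nc <- ncol(lab)
  for (p in list(p0, p1))
    if (length(p) != 2L || p[1] < 0 || p[1] > nr - 1 || p[2] < 0 ||
        p[2] > nc - 1)
      .stopf("marker line endpoints must lie inside the canvas")
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) .stopf("marker line endpoints must differ")
  ts <- seq(0, len, by = step)
  rr <- p0[1] + ts / len * (p1[1] - p0[1])
  cc <- p0[2] + ts / len * (p1[2] - p0[2])
  hit <- lab[cbind(pmin(pmax(round(rr), 0), nr - 1) + 1L,
                   pmin(pmax(round(cc), 0), nc - 1) + 1L)] == class_label
  if (!any(hit)) return(NA_real_)
  mid <- which.min(abs(ts - len / 2))
  anchor <- mid
  if (!hit[mid]) {
    near <- which(hit & abs(ts - ts[mid]) <= tolerance)
    if (!length(near)) return(NA_real_)
    anchor <- near[which.min(abs(ts[near] - ts[mid]))]
  }
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- which(starts <= anchor & ends >= anchor)
  runs$lengths[k] * step
}

#' Percent diameter stenosis
#'
#' \code{((reference - lesion) / reference) * 100}, the clinical severity
#' measure. A lesion diameter exceeding the reference yields a negative
#' value, returned as-is (clamping would bias downstream statistics).
#'
#' @param lesion_diameter lesion (minimal) diameter, mm, >= 0.
#' @param reference_diameter interpolated healthy reference diameter, mm, > 0.
#' @return Percent diameter stenosis.
#' @examples
#' percentStenosis(1.0, 2.0)  # 50
#' @export
percentStenosis <- function(lesion_diameter, reference_diameter) {
  if (!all(reference_diameter > 0))
    .stopf("reference diameter must be > 0")
  if (!all(lesion_diameter >= 0))
    .stopf("lesion diameter must be >= 0")
  (reference_diameter - lesion_diameter) / reference_diameter * 100
}

#' Measure the vessel markers of a QCA reference on a mask
#'
#' Measures the chord of the coronary class along the proximal-border,
#' lesion and distal-border marker lines, converts to mm with the
#' calibration, and computes percent stenosis against the reference
#' diameter carried by the reference record (the segmented image holds no
#' healthy-profile interpolation of its own, so the reference value is
#' reused). Any gap signal sets the marker's gap flag and marks the case
#' excluded; no silent imputation is performed.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param ref a \linkS4class{QcaReference} carrying the three vessel roles.
#' @param step chord sampling step in pixels.
#' @return list of class \code{qcaMeasurement}: \code{proximal_mm},
#'   \code{lesion_mm}, \code{distal_mm}, \code{stenosis_percent},
#'   \code{gap_flags} (named logical), \code{excluded}, \code{reason},
#'   \code{negative_stenosis}.
#' @export
measureMarkers <- function(mask, ref, step = 0.1) {
  stopifnot(is(mask, "SegmentationMask"), is(ref, "QcaReference"))
  mk <- ref@markers
  missing_roles <- setdiff(.VESSEL_ROLES, mk$role)
  if (length(missing_roles))
    .stopf("invalid-reference: missing vessel marker role(s): %s",
           paste(missing_roles, collapse = ", "))
  px <- vapply(.VESSEL_ROLES, function(role) {
    m <- mk[mk$role == role, ]
    chordLength(mask, c(m$r0, m$c0), c(m$r1, m$c1), 1L, step = step)
  }, numeric(1))
  mm <- px * ref@calibration
  gap <- is.na(mm)
  names(gap) <- .VESSEL_ROLES
  sten <- if (gap[["lesion"]]) NA_real_ else
    percentStenosis(mm[["lesion"]], ref@referenceDiameter)
  reason <- if (any(gap))
    paste0("gap:", sub("_border", "", .VESSEL_ROLES[gap]), collapse = ",")
  else ""
  structure(list(proximal_mm = mm[["proximal_border"]],
                 lesion_mm = mm[["lesion"]],
                 distal_mm = mm[["distal_border"]],
                 stenosis_percent = sten,
                 gap_flags = gap,
                 excluded = any(gap),
                 reason = reason,
                 negative_stenosis = isTRUE(sten < 0)),
            class = "qcaMeasurement")
}

#' @export
print.qcaMeasurement <- function(x, ...) {
  cat("QCA caliper measurement:\n")
  cat(sprintf("  proximal %.3f mm, lesion %.3f mm, distal %.3f mm, stenosis %.1f%%\n",
              x$proximal_mm, x$lesion_mm, x$distal_mm, x$stenosis_percent))
  if (x$excluded) cat("  EXCLUDED:", x$reason, "\n")
  invisible(x)
}

#' Measure the catheter diameter
#'
#' On a segmented mask (\code{arm = "segmented"}), measures the
#' catheter-class chord along a probe line perpendicular to, and midway
#' between, the two parallel caliper lines. On the reference record
#' (\code{arm = "reference"}), returns the perpendicular distance between
#' the two parallel lines times the calibration, mirroring automatic border
#' detection on the original image. A gap in the catheter class signals
#' exclusion (\code{NA}), mirroring catheter sub-study exclusions for
#' segmentation gaps.
#'
#' @param mask a \linkS4class{SegmentationMask} (ignored for the reference
#'   arm).
#' @param ref a \linkS4class{QcaReference} with both catheter caliper lines.
#' @param arm \code{"segmented"} or \code{"reference"}.
#' @param step chord sampling step in pixels.
#' @return Catheter diameter in mm, or \code{NA} when the catheter class is
#'   absent along the probe (exclusion, reason "gap:catheter").
#' @export
measureCatheter <- function(mask, ref, arm = c("segmented", "reference"),
                            step = 0.1) {
  arm <- match.arg(arm)
  stopifnot(is(ref, "QcaReference"))
  mk <- ref@markers
  if (!all(.CATH_ROLES %in% mk$role))
    .stopf("invalid-reference: both catheter caliper lines must be present")
  a <- mk[mk$role == "catheter_caliper_a", ]
  b <- mk[mk$role == "catheter_caliper_b", ]
  va <- c(a$r1 - a$r0, a$c1 - a$c0)
  vb <- c(b$r1 - b$r0, b$c1 - b$c0)
  ang <- acos(pmin(1, abs(sum(va * vb)) / sqrt(sum(va^2) * sum(vb^2))))
  if (ang > 2 * pi / 180)
    .stopf("invalid-reference: catheter caliper lines are not parallel within 2 degrees")
  ua <- va / sqrt(sum(va^2))
  nrm <- c(-ua[2], ua[1])
  mida <- c(a$r0 + a$r1, a$c0 + a$c1) / 2
  midb <- c(b$r0 + b$r1, b$c0 + b$c1) / 2
  sep <- abs(sum((midb - mida) * nrm))
  if (arm == "reference") return(sep * ref@calibration)

  stopifnot(is(mask, "SegmentationMask"))
  centre <- (mida + midb) / 2
  h <- sep * 1.5 + 3
  nr <- nrow(mask@labels); nc <- ncol(mask@labels)
  clamp <- function(p) c(min(max(p[1], 0), nr - 1), min(max(p[2], 0), nc - 1))
  p0 <- clamp(centre - h * nrm)
  p1 <- clamp(centre + h * nrm)
  px <- chordLength(mask, p0, p1, class_label = 2L, step = step)
  if (is.na(px)) return(NA_real_)
  px * ref@calibration
}

#' Convert a French catheter gauge to millimetres
#'
#' 1 Fr = 1/3 mm outer diameter (the standard catheter gauge definition).
#'
#' @param french_size positive integer gauge.
#' @return Diameter in mm (\code{french_size / 3}).
#' @examples
#' frenchToMm(6)  # 2 mm
#' @export
frenchToMm <- function(french_size) {
  if (!all(french_size >= 1))
    .stopf("french_size must be >= 1")
  french_size / 3
}

#' Image calibration from a measured catheter width
#'
#' When DICOM calibration metadata is unavailable, the catheter of known
#' French size serves as the in-image ruler: mm/pixel = known diameter /
#' measured width.
#'
#' @param measured_px measured catheter width in pixels, > 0.
#' @param french_size catheter gauge in French.
#' @return Calibration in mm/pixel.
#' @examples
#' calibrationFromCatheter(10, 6)  # 0.2 mm/px
#' @export
calibrationFromCatheter <- function(measured_px, french_size) {
  if (!all(measured_px > 0))
    .stopf("measured catheter width must be > 0 pixels")
  frenchToMm(french_size) / measured_px
}
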