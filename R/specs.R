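# Specification records for the phantom generator. These are lightweight
# validated lists (the heavyweight S4 classes are reserved for the data
# objects the pipeline passes around).

#' Catheter specification
#'
#' @param french_size catheter gauge in French (5 or 6); diameter in mm is
#'   \code{french_size / 3}.
#' @param centerline numeric matrix (n x 2) of 0-based (row, col) control
#'   points; the last point is the catheter tip, where it meets the vessel
#'   origin.
#' @return A validated \code{CatheterSpec} list.
#' @export
catheterSpec <- function(french_size, centerline) {
  french_size <- as.integer(french_size)
  if (!(french_size %in% c(5L, 6L)))
    .stopf("invalid-spec: french_size must be 5 or 6, got %d", french_size)
  centerline <- .asControlPoints(centerline, "catheter centerline")
  structure(list(french_size = french_size, centerline = centerline,
                 tip = centerline[nrow(centerline), ]),
            class = "CatheterSpec")
}

#' Branch specification for a vessel tree
#'
#' @param attach_mm arc position (mm along the main centerline) where the
#'   branch attaches.
#' @param fraction branch diameter as a fraction of the local parent
#'   diameter, in (0, 1).
#' @param centerline (n x 2) control points of the branch path, 0-based
#'   (row, col); the attachment point is prepended automatically.
#' @return A validated \code{BranchSpec} list.
#' @export
branchSpec <- function(attach_mm, fraction, centerline) {
  if (!(is.numeric(fraction) && length(fraction) == 1L && fraction > 0 &&
        fraction < 1))
    .stopf("invalid-spec: branch diameter fraction must lie in (0, 1)")
  if (!(is.numeric(attach_mm) && attach_mm >= 0))
    .stopf("invalid-spec: branch attachment arc position must be >= 0 mm")
  structure(list(attach_mm = attach_mm, fraction = fraction,
                 centerline = .asControlPoints(centerline, "branch centerline")),
            class = "BranchSpec")
}

#' Vessel tree specification
#'
#' Describes the analytic geometry of a synthetic coronary tree: a main
#' vessel whose local diameter tapers linearly with arc length,
#' \eqn{d(s) = d_0 (1 - \tau s)}, optional side branches, and a catheter of
#' known French size.
#'
#' @param canvas integer(2), canvas size in pixels (rows, cols), at least
#'   64 x 64.
#' @param spacing pixel spacing in mm/pixel (isotropic), > 0.
#' @param centerline (n x 2) matrix of 0-based (row, col) control points of
#'   the main vessel, interpolated with a natural spline.
#' @param baseline_diameter vessel diameter at the origin, mm.
#' @param taper_rate fraction of diameter lost per mm of arc length
#'   (0 = cylinder); the taper must keep the diameter positive over the
#'   whole arc (checked at generation time against the realized arc length).
#' @param branches list of \code{\link{branchSpec}} records.
#' @param catheter a \code{\link{catheterSpec}} or NULL for no catheter.
#' @return A validated \code{VesselTreeSpec} list.
#' @examples
#' tree <- vesselTreeSpec(canvas = c(128, 128), spacing = 0.1,
#'                        centerline = rbind(c(64, 10), c(64, 118)),
#'                        baseline_diameter = 2.5, taper_rate = 0)
#' @export
vesselTreeSpec <- function(canvas, spacing, centerline, baseline_diameter,
                           taper_rate = 0, branches = list(),
                           catheter = NULL) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 2L || any(canvas < 64L))
    .stopf("invalid-spec: canvas must be at least 64x64 pixels")
  if (!(is.numeric(spacing) && length(spacing) == 1L && spacing > 0))
    .stopf("invalid-spec: pixel_spacing must be > 0")
  if (!(is.numeric(baseline_diameter) && baseline_diameter > 0))
    .stopf("invalid-spec: baseline_diameter must be > 0")
  if (!(is.numeric(taper_rate) && taper_rate >= 0))
    .stopf("invalid-spec: taper_rate must be >= 0")
  if (!all(vapply(branches, inherits, logical(1), "BranchSpec")))
    .stopf("invalid-spec: branches must be a list of branchSpec records")
  if (!is.null(catheter) && !inherits(catheter, "CatheterSpec"))
    .stopf("invalid-spec: catheter must be a catheterSpec or NULL")
  structure(list(canvas = canvas, spacing = spacing,
                 centerline = .asControlPoints(centerline, "main centerline"),
                 baseline_diameter = baseline_diameter,
                 taper_rate = taper_rate, branches = branches,
                 catheter = catheter),
            class = "VesselTreeSpec")
}

#' Focal stenosis specification
#'
#' The lesion is a smooth raised-cosine narrowing of the local diameter over
#' \code{length_mm} of arc, reaching a fractional diameter reduction of
#' \code{severity} at its centre. The clinically targeted range is
#' 0.5--0.99 (visual 50--99\% lesions), with milder lesions down to 0.3
#' representing cases that QCA re-grades below 50\%; severity 0 is accepted
#' as the degenerate no-lesion case.
#'
#' @param position_mm arc position of the lesion centre, mm along the main
#'   centerline.
#' @param severity fractional diameter reduction in \[0, 0.99\].
#' @param length_mm length of the narrowed zone, mm.
#' @return A validated \code{StenosisSpec} list.
#' @export
stenosisSpec <- function(position_mm, severity, length_mm = 8) {
  if (!(is.numeric(severity) && length(severity) == 1L && severity >= 0 &&
        severity <= 0.99))
    .stopf("invalid-spec: stenosis severity must lie in [0, 0.99]")
  if (!(is.numeric(position_mm) && position_mm > 0))
    .stopf("invalid-spec: stenosis arc position must be > 0 mm")
  if (!(is.numeric(length_mm) && length_mm > 0))
    .stopf("invalid-spec: stenosis length must be > 0 mm")
  structure(list(position_mm = position_mm, severity = severity,
                 length_mm = length_mm),
            class = "StenosisSpec")
}

#' Degradation specification: the defect profile of a simulated segmenter
#'
#' Emulates the characteristic imperfections of automatic coronary
#' segmentation: a systematic over/under-segmentation bias, random boundary
#' jitter, gaps in the distal parts of small collaterals, a catheter gap near
#' the tip (contrast backflow), and small false-positive blobs.
#'
#' @param boundary_jitter_sigma sd (pixels) of the random boundary
#'   displacement field applied to the coronary class.
#' @param diameter_bias signed systematic boundary displacement in pixels
#'   (positive = over-segmentation). Without jitter, sub-pixel magnitudes
#'   below 0.5 px cannot alter a binary mask; with jitter the bias acts as
#'   the mean displacement.
#' @param collateral_gap_rate probability, per branch, of a distal gap.
#' @param collateral_gap_length gap length along the branch, mm.
#' @param catheter_gap_rate probability of a gap near the catheter tip.
#' @param catheter_gap_length catheter gap length, mm.
#' @param fp_blob_rate expected number of false-positive blobs per image
#'   (Poisson).
#' @param fp_blob_diameter blob diameter, pixels.
#' @param seed optional default RNG seed used by \code{\link{degradeMask}}.
#' @return A validated \code{DegradationSpec} list. The all-zero default is
#'   the identity degradation.
#' @export
degradationSpec <- function(boundary_jitter_sigma = 0, diameter_bias = 0,
                            collateral_gap_rate = 0,
                            collateral_gap_length = 0,
                            catheter_gap_rate = 0, catheter_gap_length = 0,
                            fp_blob_rate = 0, fp_blob_diameter = 6,
                            seed = NULL) {
  rates <- c(collateral_gap_rate = collateral_gap_rate,
             catheter_gap_rate = catheter_gap_rate)
  if (any(rates < 0 | rates > 1))
    .stopf("invalid-spec: gap rates must lie in [0, 1]")
  if (boundary_jitter_sigma < 0)
    .stopf("invalid-spec: boundary_jitter_sigma must be >= 0")
  if (collateral_gap_length < 0 || catheter_gap_length < 0)
    .stopf("invalid-spec: gap lengths must be >= 0")
  if (fp_blob_rate < 0)
    .stopf("invalid-spec: fp_blob_rate must be >= 0")
  if (fp_blob_diameter <= 0)
    .stopf("invalid-spec: fp_blob_diameter must be > 0")
  structure(list(boundary_jitter_sigma = boundary_jitter_sigma,
                 diameter_bias = diameter_bias,
                 collateral_gap_rate = collateral_gap_rate,
                 collateral_gap_length = collateral_gap_length,
                 catheter_gap_rate = catheter_gap_rate,
                 catheter_gap_length = catheter_gap_length,
                 fp_blob_rate = fp_blob_rate,
                 fp_blob_diameter = fp_blob_diameter,
                 seed = seed),
            class = "DegradationSpec")
}

.asControlPoints <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 2L || nrow(x) < 2L || any(!is.finite(x)))
    .stopf("invalid-spec: %s must be an (n >= 2) x 2 matrix of finite (row, col) points",
           what)
  keep <- c(TRUE, rowSums(abs(diff(x))) > 1e-9)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L)
    .stopf("invalid-spec: %s collapses to a single point", what)
  dimnames(x) <- NULL
  x
}
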