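# Canonical and randomized phantom geometries. The fixed values here define
# the study conditions the synthetic cohort is generated under; the vignette
# documents why each was chosen.

#' A canonical deterministic vessel tree
#'
#' A gently curving main vessel crossing a 512 x 512 canvas at 0.1 mm/px
#' (about a 5 cm field of view, the working resolution of a magnified
#' angiographic acquisition), baseline diameter 3 mm tapering at 0.008 per
#' mm, two distal branches, and a 6 Fr catheter entering from the top edge.
#'
#' @param canvas integer(2) canvas size.
#' @param spacing mm per pixel.
#' @return A \code{\link{vesselTreeSpec}}.
#' @export
defaultTreeSpec <- function(canvas = c(512L, 512L), spacing = 0.1) {
  sc <- canvas / 512  # keep the layout proportional on smaller canvases
  main <- cbind(c(45, 130, 250, 370, 465) * sc[1],
                c(120, 185, 235, 270, 320) * sc[2])
  br1 <- cbind(c(295, 360, 430) * sc[1], c(140, 95, 70) * sc[2])
  br2 <- cbind(c(420, 465, 480) * sc[1], c(330, 380, 430) * sc[2])
  # the catheter enters at the left edge and engages the vessel origin
  cath <- cbind(c(45, 45, 45) * sc[1], c(0, 60, 120) * sc[2])
  arc_attach <- function(frac) {
    g <- .interpCenterline(main, spacing)
    frac * g$arc_mm
  }
  vesselTreeSpec(canvas = canvas, spacing = spacing, centerline = main,
                 baseline_diameter = 3.0, taper_rate = 0.008,
                 branches = list(
                   branchSpec(arc_attach(0.55), 0.55, br1),
                   branchSpec(arc_attach(0.78), 0.5, br2)),
                 catheter = catheterSpec(6L, cath))
}

#' A randomized vessel tree for cohort generation
#'
#' Perturbs the canonical layout: random origin, lateral drift of the main
#' centerline, one or two distal branches with random take-off and caliber,
#' and a 5 or 6 Fr catheter. Control points are kept inside a safety margin
#' so the coronary tube cannot leave the canvas.
#'
#' @param seed integer seed; the same seed always returns the same tree.
#' @param canvas integer(2) canvas size.
#' @param spacing mm per pixel.
#' @param n_branches number of side branches (0, 1 or 2).
#' @return A \code{\link{vesselTreeSpec}}.
#' @export
randomTreeSpec <- function(seed, canvas = c(512L, 512L), spacing = 0.1,
                           n_branches = 2L) {
  set.seed(.subSeed(seed, 11L))
  nr <- canvas[1]; nc <- canvas[2]
  margin <- max(26, round(0.1 * min(canvas)))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  # a branch whose clamped control points collapse is dropped, not distorted
  sane <- function(pts) all(sqrt(rowSums(diff(pts)^2)) > 3)
  baseline <- stats::runif(1, 2.7, 3.3)
  # lateral corridor wide enough that marker lines (half-length about
  # 1.5 x the local diameter) stay on the canvas wherever the lesion lands
  lat <- min(max(margin, ceiling(1.7 * baseline / spacing)),
             floor(nc / 2) - 10)
  r0 <- stats::runif(1, 0.07, 0.13) * nr
  c0 <- stats::runif(1, 0.2, 0.4) * nc
  rows <- seq(r0, 0.92 * nr, length.out = 5)
  drift <- cumsum(stats::runif(4, -0.12, 0.16) * nc)
  cols <- clamp(c0 + c(0, drift), lat, nc - lat)
  main <- cbind(rows, cols)

  g <- .interpCenterline(main, spacing)
  branches <- list()
  if (n_branches >= 1L) {
    att <- stats::runif(1, 0.5, 0.62) * g$arc_mm
    fr <- .arcFrame(g, att)
    side <- sample(c(-1, 1), 1)
    len <- stats::runif(1, 120, 180)
    dirv <- fr$tangent * 0.55 + side * fr$normal * 0.85
    dirv <- dirv / sqrt(sum(dirv^2))
    pts <- rbind(fr$p + len * 0.5 * dirv + c(0, side * 12),
                 fr$p + len * dirv)
    pts[, 1] <- clamp(pts[, 1], margin, nr - margin)
    pts[, 2] <- clamp(pts[, 2], margin, nc - margin)
    if (sane(rbind(fr$p, pts)))
      branches <- c(branches,
                    list(branchSpec(att, stats::runif(1, 0.45, 0.65), pts)))
  }
  if (n_branches >= 2L) {
    att <- stats::runif(1, 0.72, 0.82) * g$arc_mm
    fr <- .arcFrame(g, att)
    side <- sample(c(-1, 1), 1)
    len <- stats::runif(1, 90, 140)
    dirv <- fr$tangent * 0.6 + side * fr$normal * 0.8
    dirv <- dirv / sqrt(sum(dirv^2))
    pts <- rbind(fr$p + len * 0.5 * dirv, fr$p + len * dirv)
    pts[, 1] <- clamp(pts[, 1], margin, nr - margin)
    pts[, 2] <- clamp(pts[, 2], margin, nc - margin)
    if (sane(rbind(fr$p, pts)))
      branches <- c(branches,
                    list(branchSpec(att, stats::runif(1, 0.4, 0.6), pts)))
  }

  french <- sample(c(5L, 6L), 1)
  c0m <- main[1, 2]
  cath <- cbind(c(0, r0 / 2, r0),
                clamp(c(c0m - 25, c0m - 12, c0m), 30, nc - 30))
  vesselTreeSpec(canvas = canvas, spacing = spacing, centerline = main,
                 baseline_diameter = baseline,
                 taper_rate = stats::runif(1, 0.006, 0.01),
                 branches = branches,
                 catheter = catheterSpec(french, cath))
}

#' Arc length of the main vessel centerline
#'
#' Useful for placing a stenosis at a fraction of the vessel course.
#'
#' @param tree a \code{\link{vesselTreeSpec}}.
#' @return Arc length in mm.
#' @export
mainArcLength <- function(tree) {
  stopifnot(inherits(tree, "VesselTreeSpec"))
  .interpCenterline(tree$centerline, tree$spacing)$arc_mm
}
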