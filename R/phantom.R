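# Phantom module: synthetic angiogram-like label masks with known vessel
# geometry, a focal stenosis, a catheter, a CAAS-style reference record and
# a controlled degraded "prediction" mask.

#' Generate a synthetic phantom case
#'
#' Rasterizes the vessel tree from its analytic geometry (local diameter
#' \eqn{d(s) = d_0 (1 - \tau s)} modulated by a raised-cosine stenosis
#' notch), builds the QCA-style reference (three marker lines, reference
#' diameter, catheter calipers, calibration), computes the analytic truth
#' record, and degrades the truth mask into a simulated model prediction.
#' Identical specs and seed give bit-identical output.
#'
#' @param tree a \code{\link{vesselTreeSpec}}.
#' @param stenosis a \code{\link{stenosisSpec}}.
#' @param degradation a \code{\link{degradationSpec}}; the all-zero default
#'   returns a prediction identical to the truth.
#' @param seed integer RNG seed for the degradation sub-streams.
#' @return A \linkS4class{PhantomCase}. Cases whose lesion diameter falls
#'   below 2 pixels carry a \code{"resolution-limit"} warning flag in their
#'   provenance.
#' @examples
#' tree <- vesselTreeSpec(canvas = c(128, 128), spacing = 0.1,
#'                        centerline = rbind(c(64, 10), c(64, 118)),
#'                        baseline_diameter = 2.0, taper_rate = 0)
#' ph <- generatePhantom(tree, stenosisSpec(6, 0.5, 4), seed = 1)
#' truthRecord(ph)
#' @export
generatePhantom <- function(tree, stenosis,
                            degradation = degradationSpec(), seed = 1L) {
  stopifnot(inherits(tree, "VesselTreeSpec"),
            inherits(stenosis, "StenosisSpec"),
            inherits(degradation, "DegradationSpec"))
  geom <- .buildGeometry(tree, stenosis)
  labels <- .rasterizeTree(tree, geom)
  truth <- SegmentationMask(labels, tree$spacing)

  rec <- .truthRecord(tree, stenosis, geom)
  warnings <- character()
  if (rec[["lesion_mm"]] < 2 * tree$spacing)
    warnings <- c(warnings, "resolution-limit")

  ref <- .makeQcaReference(tree, stenosis, geom, truth)
  predicted <- degradeMask(truth, degradation, geometry = geom, seed = seed)

  new("PhantomCase", truth = truth, predicted = predicted, reference = ref,
      truthRecord = rec, geometry = geom,
      provenance = list(tree = tree, stenosis = stenosis,
                        degradation = degradation, seed = seed,
                        warnings = warnings))
}

# Dense centerlines + diameter profiles for the whole tree.
.buildGeometry <- function(tree, stenosis) {
  main <- .interpCenterline(tree$centerline, tree$spacing)
  if (!is.null(stenosis)) {
    lo <- stenosis$position_mm - stenosis$length_mm / 2
    hi <- stenosis$position_mm + stenosis$length_mm / 2
    if (lo <= 0 || hi >= main$arc_mm)
      .stopf("invalid-spec: stenosis window [%.1f, %.1f] mm must lie inside the vessel arc (%.1f mm)",
             lo, hi, main$arc_mm)
  }
  main$healthy_mm <- .healthyDiameter(main$s_mm, tree$baseline_diameter,
                                      tree$taper_rate)
  if (any(main$healthy_mm <= 0))
    .stopf("invalid-spec: taper drives the vessel diameter to zero within the arc")
  main$diam_mm <- main$healthy_mm * .notchFactor(main$s_mm, stenosis)

  branches <- lapply(tree$branches, function(br) {
    if (br$attach_mm >= main$arc_mm)
      .stopf("invalid-spec: branch attaches at %.1f mm, beyond the %.1f mm arc",
             br$attach_mm, main$arc_mm)
    at <- .arcFrame(main, br$attach_mm)
    d0 <- .healthyDiameter(br$attach_mm, tree$baseline_diameter,
                           tree$taper_rate) * br$fraction
    g <- .interpCenterline(rbind(at$p, br$centerline), tree$spacing)
    g$diam_mm <- .healthyDiameter(g$s_mm, d0, tree$taper_rate)
    if (any(g$diam_mm <= 0))
      .stopf("invalid-spec: branch taper drives its diameter to zero")
    g
  })

  catheter <- NULL
  if (!is.null(tree$catheter)) {
    catheter <- .interpCenterline(tree$catheter$centerline, tree$spacing)
    catheter$diam_mm <- rep(frenchToMm(tree$catheter$french_size),
                            length(catheter$row))
  }
  list(main = main, branches = branches, catheter = catheter,
       spacing = tree$spacing, canvas = tree$canvas)
}

.rasterizeTree <- function(tree, geom) {
  labels <- matrix(0L, tree$canvas[1], tree$canvas[2])
  px <- function(mm) mm / tree$spacing
  if (!is.null(geom$catheter)) {
    g <- geom$catheter
    labels <- .stampDisks(labels, g$row, g$col, px(g$diam_mm) / 2, 2L)
  }
  # the coronary tree must stay inside the canvas; the catheter may enter
  # from the image border, as catheters do
  for (g in c(list(geom$main), geom$branches)) {
    if (!.tubeContained(tree$canvas, g$row, g$col, px(g$diam_mm) / 2))
      .stopf("invalid-spec: coronary geometry leaves the canvas")
    labels <- .stampDisks(labels, g$row, g$col, px(g$diam_mm) / 2, 1L)
  }
  labels
}

# Analytic truth record; never measured from pixels. The raised-cosine
# notch is 1 at the lesion borders, so border diameters equal the healthy
# profile there and the stenosis equals severity * 100 by construction.
.truthRecord <- function(tree, stenosis, geom) {
  h <- function(s) .healthyDiameter(s, tree$baseline_diameter,
                                    tree$taper_rate)
  s0 <- stenosis$position_mm
  half <- stenosis$length_mm / 2
  ref <- h(s0)
  lesion <- ref * (1 - stenosis$severity)
  c(proximal_mm = h(s0 - half), lesion_mm = lesion, distal_mm = h(s0 + half),
    reference_mm = ref,
    stenosis_percent = (ref - lesion) / ref * 100)
}

#' Build the CAAS-style QCA reference for a phantom
#'
#' Places three marker lines perpendicular to the main centerline at the
#' proximal border, lesion centre and distal border of the stenosis, each
#' extending beyond the truth vessel boundary by at least 3 pixels on both
#' sides (half-length 1.5 x the local healthy diameter). The reference
#' diameter is the analytic healthy-profile diameter at the lesion centre
#' and the calibration equals the pixel spacing. When the tree carries a
#' catheter, two parallel caliper lines are laid along the catheter edges
#' near its tip, mirroring automatic border detection on the original image.
#'
#' @inheritParams generatePhantom
#' @return A \linkS4class{QcaReference}.
#' @export
makeQcaReference <- function(tree, stenosis) {
  stopifnot(inherits(tree, "VesselTreeSpec"),
            inherits(stenosis, "StenosisSpec"))
  geom <- .buildGeometry(tree, stenosis)
  .makeQcaReference(tree, stenosis, geom, NULL)
}

.makeQcaReference <- function(tree, stenosis, geom, truth) {
  spacing <- tree$spacing
  s0 <- stenosis$position_mm
  half <- stenosis$length_mm / 2
  roles <- c(proximal_border = s0 - half, lesion = s0, distal_border = s0 + half)
  rows <- lapply(names(roles), function(role) {
    fr <- .arcFrame(geom$main, roles[[role]])
    d_px <- geom$main$healthy_mm[fr$i] / spacing
    h <- max(1.5 * d_px, d_px / 2 + 4)
    p0 <- fr$p - h * fr$normal
    p1 <- fr$p + h * fr$normal
    for (p in list(p0, p1))
      if (p[1] < 0 || p[1] > tree$canvas[1] - 1 ||
          p[2] < 0 || p[2] > tree$canvas[2] - 1)
        .stopf("invalid-spec: %s marker line exits the canvas", role)
    data.frame(role = role, r0 = p0[1], c0 = p0[2], r1 = p1[1], c1 = p1[2])
  })
  markers <- do.call(rbind, rows)

  french <- NA_integer_
  if (!is.null(geom$catheter)) {
    french <- tree$catheter$french_size
    g <- geom$catheter
    r_px <- frenchToMm(french) / 2 / spacing
    # anchor proximal of the tip, clear of the vessel-origin junction where
    # the coronary class overwrites the catheter
    clear_mm <- tree$baseline_diameter / 2 + (r_px + 8) * spacing
    s_anchor <- max(g$arc_mm - clear_mm, 0.35 * g$arc_mm)
    fr <- .arcFrame(g, s_anchor)
    hl <- 8  # caliper half-length along the catheter axis, px
    for (side in c(-1, 1)) {
      ctr <- fr$p + side * r_px * fr$normal
      p0 <- ctr - hl * fr$tangent
      p1 <- ctr + hl * fr$tangent
      markers <- rbind(markers, data.frame(
        role = if (side < 0) "catheter_caliper_a" else "catheter_caliper_b",
        r0 = p0[1], c0 = p0[2], r1 = p1[1], c1 = p1[2]))
    }
  }
  ref_mm <- .healthyDiameter(s0, tree$baseline_diameter, tree$taper_rate)
  QcaReference(markers, reference_diameter = ref_mm, calibration = spacing,
               catheter_french = french)
}

#' Degrade a truth mask into a simulated model prediction
#'
#' Applies, in order: a combined boundary operator (systematic diameter
#' bias + per-pixel boundary jitter, implemented as thresholding of the
#' signed distance field of the coronary class plus a seed-fixed Gaussian
#' field), collateral gaps in the distal half of each branch, a catheter gap
#' near the tip, and false-positive blobs placed off-vessel. Deterministic
#' under a fixed seed; each defect type draws from its own RNG sub-stream,
#' so toggling one defect leaves the others' draws unchanged. A degenerate
#' all-zero spec returns an identical mask.
#'
#' @param mask a \linkS4class{SegmentationMask} (the truth).
#' @param spec a \code{\link{degradationSpec}}.
#' @param geometry internal geometry list from \code{\link{generatePhantom}};
#'   required for branch/catheter gap placement (gap defects are skipped
#'   with a warning when it is absent).
#' @param seed integer RNG seed; defaults to \code{spec$seed}.
#' @return The degraded \linkS4class{SegmentationMask}.
#' @export
degradeMask <- function(mask, spec, geometry = NULL, seed = spec$seed) {
  stopifnot(is(mask, "SegmentationMask"), inherits(spec, "DegradationSpec"))
  seed <- as.integer(seed %||% 1L)
  labels <- mask@labels
  spacing <- mask@spacing
  px <- function(mm) mm / spacing

  # -- boundary operator: bias + jitter on the coronary class ------------
  if (spec$diameter_bias != 0 || spec$boundary_jitter_sigma > 0) {
    cor <- labels == 1L
    if (any(cor) && !all(cor)) {
      sdf <- .signedDistance(cor)
      z <- 0
      if (spec$boundary_jitter_sigma > 0) {
        set.seed(.subSeed(seed, 1L))
        z <- spec$boundary_jitter_sigma * .smoothField(dim(labels))
      }
      newcor <- (sdf - spec$diameter_bias + z) < 0
      editable <- labels != 2L  # never rewrite the catheter
      labels[editable] <- ifelse(newcor[editable], 1L, 0L)
    }
  }

  # -- collateral gaps (distal half of each branch) ----------------------
  if (spec$collateral_gap_rate > 0 && spec$collateral_gap_length > 0) {
    if (is.null(geometry)) {
      warning("collateral gaps need the phantom geometry; skipped")
    } else {
      set.seed(.subSeed(seed, 2L))
      for (g in geometry$branches) {
        if (stats::runif(1) >= spec$collateral_gap_rate) next
        centre <- stats::runif(1, 0.55, 0.9) * g$arc_mm
        win <- abs(g$s_mm - centre) <= spec$collateral_gap_length / 2
        labels <- .stampDisks(labels, g$row[win], g$col[win],
                              px(g$diam_mm[win]) / 2 + 1.5, 0L,
                              only = 1L)
      }
    }
  }

  # -- catheter gap near the tip (contrast backflow) ---------------------
  if (spec$catheter_gap_rate > 0 && spec$catheter_gap_length > 0) {
    if (is.null(geometry)) {
      warning("the catheter gap needs the phantom geometry; skipped")
    } else if (!is.null(geometry$catheter)) {
      set.seed(.subSeed(seed, 3L))
      if (stats::runif(1) < spec$catheter_gap_rate) {
        g <- geometry$catheter
        hi <- g$arc_mm - 1
        win <- g$s_mm >= hi - spec$catheter_gap_length & g$s_mm <= hi
        labels <- .stampDisks(labels, g$row[win], g$col[win],
                              px(g$diam_mm[win]) / 2 + 1.5, 0L,
                              only = 2L)
      }
    }
  }

  # -- false-positive blobs, off-vessel ----------------------------------
  if (spec$fp_blob_rate > 0) {
    set.seed(.subSeed(seed, 4L))
    n <- stats::rpois(1, spec$fp_blob_rate)
    if (n > 0) {
      fg <- labels > 0L
      rad <- spec$fp_blob_diameter / 2
      if (any(fg)) {
        clearance <- .distToForeground(fg)
      } else {
        clearance <- matrix(Inf, nrow(labels), ncol(labels))
      }
      idx <- which(clearance >= spec$fp_blob_diameter + 2)
      if (length(idx)) {
        rr <- (idx - 1L) %% nrow(labels)
        cc <- (idx - 1L) %/% nrow(labels)
        inb <- rr >= rad & rr <= nrow(labels) - 1 - rad &
          cc >= rad & cc <= ncol(labels) - 1 - rad
        idx <- idx[inb]
        if (length(idx)) {
          pick <- sample(length(idx), min(n, length(idx)),
                         replace = length(idx) < n)
          labels <- .stampDisks(labels, (idx[pick] - 1L) %% nrow(labels),
                                (idx[pick] - 1L) %/% nrow(labels),
                                rep(rad, length(pick)), 1L, only = 0L)
        }
      }
    }
  }

  SegmentationMask(labels, spacing)
}

# Unit-variance spatially correlated Gaussian field (correlation length a
# few pixels). Segmentation errors are coherent along the boundary, not
# salt-and-pepper, so the jitter displacement field is smoothed before
# thresholding; the caller scales it by sigma.
.smoothField <- function(d, corr_px = 2) {
  z <- matrix(stats::rnorm(prod(d)), d[1], d[2])
  z <- EBImage::gblur(z, sigma = corr_px)
  z / stats::sd(z)
}

# Signed distance to the coronary boundary at pixel centres: negative
# inside, positive outside, +/-0.5 on the first pixel layer either side.
.signedDistance <- function(fg) {
  din <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg)))
  dout <- EBImage::distmap(matrix(as.numeric(!fg), nrow(fg)))
  sdf <- matrix(0, nrow(fg), ncol(fg))
  sdf[fg] <- -(din[fg] - 0.5)
  sdf[!fg] <- dout[!fg] - 0.5
  sdf
}

# Distance from each pixel to the nearest foreground pixel (0 on fg).
.distToForeground <- function(fg) {
  EBImage::distmap(matrix(as.numeric(!fg), nrow(fg)))
}

#' Calibrate the degradation to a target Dice score
#'
#' Bisection on \code{boundary_jitter_sigma} (all other defect fields taken
#' from the template) until the realized whole-image coronary Dice between
#' the truth and the degraded mask is within tolerance of the target. Under
#' a fixed seed the jitter field is fixed and realized Dice is monotone
#' non-increasing in sigma, so the bisection is well-posed.
#'
#' @param truth the truth \linkS4class{SegmentationMask}.
#' @param target_dice target Dice as a fraction in (0.5, 1\].
#' @param template a \code{\link{degradationSpec}} supplying the non-jitter
#'   defects.
#' @param seed integer RNG seed used for every trial degradation.
#' @param geometry optional phantom geometry (needed if the template has
#'   gap defects).
#' @param tol convergence tolerance on realized Dice (default 0.02).
#' @param max_iter maximum bisection iterations (default 30).
#' @return list with \code{spec} (the calibrated DegradationSpec),
#'   \code{realized} (the realized Dice fraction) and \code{iterations}.
#'   An unreachable target raises a convergence error naming the best
#'   realized value.
#' @export
calibrateToDice <- function(truth, target_dice, template = degradationSpec(),
                            seed = 1L, geometry = NULL, tol = 0.02,
                            max_iter = 30L) {
  if (!(is.numeric(target_dice) && length(target_dice) == 1L &&
        target_dice > 0.5 && target_dice <= 1))
    .stopf("target_dice must lie in (0.5, 1]")
  evalSigma <- function(sigma) {
    sp <- template
    sp$boundary_jitter_sigma <- sigma
    pred <- degradeMask(truth, sp, geometry = geometry, seed = seed)
    cnt <- classifyPixels(truth, pred)
    with_cnt <- 2 * cnt@tp / (2 * cnt@tp + cnt@fn + cnt@fp)
    list(spec = sp, dice = with_cnt)
  }
  best <- evalSigma(0)
  iters <- 1L
  if (best$dice < target_dice - tol)
    .stopf("calibration target Dice %.3f unreachable: best realized %.3f with the template's mandatory defects",
           target_dice, best$dice)
  if (abs(best$dice - target_dice) <= tol / 2)
    return(list(spec = best$spec, realized = best$dice, iterations = iters))

  lo <- 0; hi <- 1
  at_hi <- evalSigma(hi); iters <- iters + 1L
  while (at_hi$dice > target_dice && hi < 64) {
    lo <- hi
    hi <- hi * 2
    at_hi <- evalSigma(hi); iters <- iters + 1L
  }
  if (abs(at_hi$dice - target_dice) < abs(best$dice - target_dice))
    best <- at_hi
  while (iters < max_iter) {
    mid <- (lo + hi) / 2
    at_mid <- evalSigma(mid); iters <- iters + 1L
    if (abs(at_mid$dice - target_dice) < abs(best$dice - target_dice))
      best <- at_mid
    if (abs(at_mid$dice - target_dice) <= tol / 3) break
    if (at_mid$dice > target_dice) lo <- mid else hi <- mid
  }
  if (abs(best$dice - target_dice) > tol)
    .stopf("calibration did not converge: best realized Dice %.3f for target %.3f",
           best$dice, target_dice)
  list(spec = best$spec, realized = best$dice, iterations = iters)
}
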