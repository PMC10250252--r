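# Analytic geometry internals for the phantom generator.
#
# Coordinate convention (used everywhere): 0-based (row, col), pixel centres
# at integer coordinates. A pixel belongs to a class if its centre lies
# inside the analytic shape; tubes are rasterized as the union of disks
# placed at dense centerline samples with the local radius.

# Interpolate control points into a dense centerline.
# Returns row/col samples, per-sample arc length in px and mm, and unit
# tangents. step_px controls sample density along the arc.
.interpCenterline <- function(ctrl, spacing, step_px = 0.25) {
  t0 <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  n_out <- max(8L, ceiling(t0[length(t0)] / step_px))
  tt <- seq(0, t0[length(t0)], length.out = n_out)
  if (nrow(ctrl) == 2L) {
    row <- stats::approx(t0, ctrl[, 1], xout = tt)$y
    col <- stats::approx(t0, ctrl[, 2], xout = tt)$y
  } else {
    row <- stats::spline(t0, ctrl[, 1], xout = tt, method = "natural")$y
    col <- stats::spline(t0, ctrl[, 2], xout = tt, method = "natural")$y
  }
  s_px <- c(0, cumsum(sqrt(diff(row)^2 + diff(col)^2)))
  # central-difference unit tangents
  n <- length(row)
  dr <- c(row[2] - row[1], row[3:n] - row[1:(n - 2)], row[n] - row[n - 1])
  dc <- c(col[2] - col[1], col[3:n] - col[1:(n - 2)], col[n] - col[n - 1])
  nrm <- sqrt(dr^2 + dc^2)
  nrm[nrm == 0] <- 1
  list(row = row, col = col, s_px = s_px, s_mm = s_px * spacing,
       arc_mm = s_px[n] * spacing, tr = dr / nrm, tc = dc / nrm)
}

# Healthy (un-notched) diameter profile in mm at arc positions s_mm.
.healthyDiameter <- function(s_mm, baseline, taper) {
  baseline * (1 - taper * s_mm)
}

# Raised-cosine stenosis notch factor: 1 outside the lesion window,
# dipping smoothly to (1 - severity) at the lesion centre.
.notchFactor <- function(s_mm, stenosis) {
  if (is.null(stenosis) || stenosis$severity == 0)
    return(rep(1, length(s_mm)))
  u <- s_mm - stenosis$position_mm
  f <- rep(1, length(s_mm))
  inside <- abs(u) <= stenosis$length_mm / 2
  f[inside] <- 1 - stenosis$severity *
    cos(pi * u[inside] / stenosis$length_mm)^2
  f
}

# Stamp the union of disks (rows, cols, rad_px all per-sample) onto a label
# matrix. `value` is written; `protect` lists label values never overwritten.
.stampDisks <- function(labels, rows, cols, rad_px, value,
                        protect = integer(0), only = NULL) {
  nr <- nrow(labels); nc <- ncol(labels)
  for (i in seq_along(rows)) {
    R <- rad_px[i]
    if (!is.finite(R) || R <= 0) next
    r0 <- max(1L, as.integer(ceiling(rows[i] - R)) + 1L)
    r1 <- min(nr, as.integer(floor(rows[i] + R)) + 1L)
    c0 <- max(1L, as.integer(ceiling(cols[i] - R)) + 1L)
    c1 <- min(nc, as.integer(floor(cols[i] + R)) + 1L)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    hit <- outer((rr - 1L - rows[i])^2, (cc - 1L - cols[i])^2, "+") <= R^2
    sub <- labels[rr, cc, drop = FALSE]
    keep <- hit
    if (length(protect)) keep <- keep & !matrix(sub %in% protect, nrow(sub))
    if (!is.null(only)) keep <- keep & matrix(sub %in% only, nrow(sub))
    sub[keep] <- value
    labels[rr, cc] <- sub
  }
  labels
}

# TRUE when every disk of the tube stays inside the canvas.
.tubeContained <- function(canvas, rows, cols, rad_px) {
  ok <- rows - rad_px >= 0 & rows + rad_px <= canvas[1] - 1 &
    cols - rad_px >= 0 & cols + rad_px <= canvas[2] - 1
  all(ok)
}

# Index of the centerline sample closest to arc position s_mm.
.arcIndex <- function(geom, s_mm) which.min(abs(geom$s_mm - s_mm))

# Point + unit tangent/normal at an arc position.
.arcFrame <- function(geom, s_mm) {
  i <- .arcIndex(geom, s_mm)
  list(p = c(geom$row[i], geom$col[i]),
       tangent = c(geom$tr[i], geom$tc[i]),
       normal = c(-geom$tc[i], geom$tr[i]),
       i = i)
}
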