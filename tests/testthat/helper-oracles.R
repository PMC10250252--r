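# Shared fixtures and independent oracles, built in code.

# A horizontal bar of `class` spanning pixel rows [row_lo, row_hi] across
# all columns (0-based rows).
barMask <- function(nr, nc, row_lo, row_hi, class = 1L, spacing = 0.1) {
  lab <- matrix(0L, nr, nc)
  lab[(row_lo:row_hi) + 1L, ] <- class
  SegmentationMask(lab, spacing)
}

# Brute-force per-pixel confusion counts: an explicit double loop,
# deliberately independent of the vectorized implementation.
oracleCounts <- function(ref, pred, roi = NULL, class = 1L) {
  a <- maskLabels(ref); b <- maskLabels(pred)
  if (is.null(roi))
    roi <- list(row_min = 0L, row_max = nrow(a), col_min = 0L,
                col_max = ncol(a))
  tp <- fp <- tn <- fn <- 0L
  for (r in seq(roi$row_min + 1L, roi$row_max)) {
    for (cl in seq(roi$col_min + 1L, roi$col_max)) {
      x <- a[r, cl] == class
      y <- b[r, cl] == class
      if (x && y) tp <- tp + 1L
      else if (!x && y) fp <- fp + 1L
      else if (x && !y) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Sorted-list type-6 quantile oracle (h = p*(n+1), linear interpolation).
oracleQ6 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- p * (n + 1)
  if (h <= 1) return(x[1])
  if (h >= n) return(x[n])
  k <- floor(h)
  x[k] + (h - k) * (x[k + 1] - x[k])
}

# Random small mask pair with labels in {0, 1, 2}.
randomMaskPair <- function(seed, nr = 32, nc = 32) {
  set.seed(seed)
  a <- matrix(sample(0:2, nr * nc, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
              nr, nc)
  b <- matrix(sample(0:2, nr * nc, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
              nr, nc)
  list(ref = SegmentationMask(a, 0.1), pred = SegmentationMask(b, 0.1))
}

# A small straight-vessel phantom, catheter-free, for caliper tests.
# Columns are inset so the tube end caps stay on the canvas.
straightTree <- function(diam_mm, canvas = c(96L, 128L), spacing = 0.1,
                         taper = 0) {
  vesselTreeSpec(canvas = canvas, spacing = spacing,
                 centerline = rbind(c(canvas[1] / 2, 16),
                                    c(canvas[1] / 2, canvas[2] - 17)),
                 baseline_diameter = diam_mm, taper_rate = taper)
}
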