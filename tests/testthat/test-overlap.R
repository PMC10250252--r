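# Overlap: ROI construction, confusion counts vs a brute-force oracle,
# metric formulas and degenerate denominators.

test_that("ROI from a single marker is its padded bounding box", {
  mk <- data.frame(role = "lesion", r0 = 10, c0 = 10, r1 = 20, c1 = 10)
  ref <- QcaReference(mk, 2, 0.1)
  roi <- roiFromMarkers(ref, c(64, 64), padding = 0)
  expect_identical(roi$row_min, 10L); expect_identical(roi$row_max, 21L)
  expect_identical(roi$col_min, 10L); expect_identical(roi$col_max, 11L)
  # padding beyond the canvas is clipped
  roi2 <- roiFromMarkers(ref, c(64, 64), padding = 500)
  expect_identical(roi2$row_min, 0L); expect_identical(roi2$row_max, 64L)
  expect_identical(roi2$col_min, 0L); expect_identical(roi2$col_max, 64L)
})

test_that("phantom marker ROI contains the whole lesion zone", {
  tree <- defaultTreeSpec(canvas = c(320L, 320L))
  st <- stenosisSpec(8, 0.6, 5)
  ph <- generatePhantom(tree, st, seed = 1)
  roi <- roiFromMarkers(qcaReference(ph), dim(truthMask(ph)), padding = 10)
  g <- ph@geometry$main
  zone <- abs(g$s_mm - st$position_mm) <= st$length_mm / 2
  expect_true(all(g$row[zone] >= roi$row_min & g$row[zone] < roi$row_max))
  expect_true(all(g$col[zone] >= roi$col_min & g$col[zone] < roi$col_max))
})

test_that("confusion counts match the brute-force per-pixel oracle", {
  for (s in 1:40) {
    pair <- randomMaskPair(s)
    roi <- if (s %% 2) list(row_min = 4L, row_max = 28L, col_min = 2L,
                            col_max = 30L) else NULL
    got <- classifyPixels(pair$ref, pair$pred, roi)
    want <- oracleCounts(pair$ref, pair$pred, roi)
    expect_identical(c(tp = got@tp, fp = got@fp, tn = got@tn, fn = got@fn),
                     c(tp = as.numeric(want[["tp"]]),
                       fp = as.numeric(want[["fp"]]),
                       tn = as.numeric(want[["tn"]]),
                       fn = as.numeric(want[["fn"]])))
  }
})

test_that("identity and empty-prediction cases classify as expected", {
  pair <- randomMaskPair(7)
  same <- classifyPixels(pair$ref, pair$ref)
  expect_identical(same@fp, 0); expect_identical(same@fn, 0)
  empty <- SegmentationMask(matrix(0L, 32, 32), 0.1)
  k <- sum(maskLabels(pair$ref) == 1L)
  cnt <- classifyPixels(pair$ref, empty)
  expect_identical(cnt@fn, as.numeric(k))
  expect_identical(cnt@tp, 0)
})

test_that("the seven metric formulas evaluate exactly as printed", {
  m <- overlapMetrics(OverlapCounts(90, 5, 900, 5))
  expect_equal(m@dice, 180 / 190)
  expect_equal(m@iou, 0.9)
  expect_equal(m@accuracy, 990 / 1000)
  expect_equal(m@sensitivity, 90 / 95)
  expect_equal(m@specificity, 900 / 905)
  expect_equal(m@ppv, 90 / 95)
  expect_equal(m@npv, 900 / 905)
  md <- as.data.frame(m)
  expect_equal(md$dice, 100 * 180 / 190)
  # perfect overlap
  p <- overlapMetrics(OverlapCounts(50, 0, 100, 0))
  expect_equal(c(p@sensitivity, p@ppv, p@iou, p@dice), rep(1, 4))
})

test_that("zero denominators yield NA with a warning, never zero", {
  expect_warning(m <- overlapMetrics(OverlapCounts(0, 0, 10, 5)), "PPV")
  expect_true(is.na(m@ppv))
  expect_equal(m@sensitivity, 0)
  expect_error(overlapMetrics(OverlapCounts(0, 0, 0, 0)), "zero")
})

test_that("Dice-IoU identity holds for random counts", {
  set.seed(3)
  for (i in 1:50) {
    cnt <- OverlapCounts(sample(1:500, 1), sample(0:50, 1),
                         sample(1:5000, 1), sample(0:50, 1))
    m <- overlapMetrics(cnt)
    expect_equal(m@dice, diceFromIoU(m@iou), tolerance = 1e-13)
    expect_lte(m@iou, m@dice)
  }
})

test_that("growing the ROI only adds background: accuracy never drops", {
  tree <- defaultTreeSpec(canvas = c(320L, 320L))
  ph <- generatePhantom(tree, stenosisSpec(8, 0.6, 5),
                        degradationSpec(boundary_jitter_sigma = 1),
                        seed = 6)
  ref <- qcaReference(ph)
  accs <- tns <- c()
  for (pad in c(0, 10, 30, 60, 120)) {
    roi <- roiFromMarkers(ref, dim(truthMask(ph)), padding = pad)
    m <- overlapMetrics(classifyPixels(truthMask(ph), predictedMask(ph), roi))
    accs <- c(accs, m@accuracy); tns <- c(tns, m@counts@tn)
  }
  expect_true(all(diff(tns) >= 0))
  expect_true(all(diff(accs) >= -1e-12))
})

test_that("shape mismatch and oversized ROI are rejected", {
  a <- SegmentationMask(matrix(0L, 16, 16), 0.1)
  b <- SegmentationMask(matrix(0L, 16, 20), 0.1)
  expect_error(classifyPixels(a, b), "shape")
  roi <- list(row_min = 0L, row_max = 20L, col_min = 0L, col_max = 16L)
  expect_error(classifyPixels(a, a, roi), "ROI")
})
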