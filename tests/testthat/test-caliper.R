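# Caliper: chord rule, calibration, percent stenosis, catheter measurement.

test_that("chord across a straight bar recovers its width", {
  m <- barMask(40, 40, 17, 23)  # 7 px wide, centred on row 20
  chord <- chordLength(m, c(5, 20), c(35, 20))
  expect_lt(abs(chord - 7), 0.1 + 1e-9)
  # brute-force oracle: count of in-class pixel centres along the column
  expect_identical(sum(maskLabels(m)[, 21] == 1L), 7L)
})

test_that("width recovery holds for 100 seeded bar widths from 4 to 30 px", {
  set.seed(1)
  for (i in 1:100) {
    w <- sample(4:30, 1)
    lo <- sample(5:20, 1)
    m <- barMask(64, 48, lo, lo + w - 1L)
    centre <- lo + (w - 1) / 2  # markers are centred on the vessel
    k <- min(centre, 63 - centre, w / 2 + 10)
    chord <- chordLength(m, c(centre - k, 24), c(centre + k, 24))
    expect_lt(abs(chord - w), 1 + 0.1, label = sprintf("width %d", w))
  }
})

test_that("gaps are signalled, never bridged", {
  m <- barMask(40, 40, 10, 16)
  # line entirely over background
  expect_true(is.na(chordLength(m, c(25, 5), c(38, 5))))
  # a 3 px hole at the midpoint: the off-centre tolerance (2 px) still
  # finds the adjacent run
  lab <- maskLabels(m)
  lab[(14:16) + 1L, 21] <- 0L
  m3 <- SegmentationMask(lab, 0.1)
  expect_false(is.na(chordLength(m3, c(5, 20), c(25, 20))))
  # a 5 px hole centred on the midpoint leaves no in-class sample within
  # 2 px: gap signal
  m5 <- barMask(40, 40, 8, 18)
  lab5 <- maskLabels(m5)
  lab5[(11:15) + 1L, 21] <- 0L
  m5 <- SegmentationMask(lab5, 0.1)
  expect_true(is.na(chordLength(m5, c(3, 20), c(23, 20))))
})

test_that("the chord is the run containing the midpoint, not the union of runs", {
  lab <- matrix(0L, 60, 20)
  lab[(27:33) + 1L, ] <- 1L   # 7 px run at the midpoint of the line below
  lab[(40:44) + 1L, ] <- 1L   # disjoint 5 px run farther along
  m <- SegmentationMask(lab, 0.1)
  chord <- chordLength(m, c(10, 10), c(50, 10))
  expect_lt(abs(chord - 7), 0.2)
})

test_that("percent stenosis follows the QCA formula exactly", {
  expect_equal(percentStenosis(1.0, 2.0), 50)
  expect_equal(percentStenosis(2.0, 2.0), 0)
  expect_equal(percentStenosis(0.88, 2.0), 56)
  # negative (lesion wider than reference) is reported as-is
  expect_equal(percentStenosis(2.2, 2.0), -10)
  expect_error(percentStenosis(1.0, 0), "reference")
  expect_error(percentStenosis(-0.1, 2), "lesion")
})

test_that("French gauge conversion and catheter calibration", {
  expect_equal(frenchToMm(6), 2.0)
  expect_equal(frenchToMm(5), 5 / 3)
  expect_equal(frenchToMm(3), 1.0)
  expect_error(frenchToMm(0), ">= 1")
  expect_equal(calibrationFromCatheter(10, 6), 0.2)
  expect_equal(calibrationFromCatheter(8, 6), 0.25)
  expect_equal(calibrationFromCatheter(10, 5), 1 / 6)
  expect_error(calibrationFromCatheter(0, 6), "> 0")
})

test_that("marker measurement recovers phantom stenosis and flags gaps", {
  tree <- defaultTreeSpec(canvas = c(320L, 320L))
  ph <- generatePhantom(tree, stenosisSpec(8, 0.5, 5), seed = 2)
  res <- measureMarkers(truthMask(ph), qcaReference(ph))
  expect_false(res$excluded)
  expect_lt(abs(res$stenosis_percent - 50), 5)
  # prediction identical to truth -> identical measurement
  res2 <- measureMarkers(predictedMask(ph), qcaReference(ph))
  expect_identical(res, res2)
})

test_that("a gap at the lesion marker excludes the case with reason gap:lesion", {
  tree <- straightTree(2.0)
  ph <- generatePhantom(tree, stenosisSpec(6, 0.5, 4), seed = 1)
  lab <- maskLabels(truthMask(ph))
  mk <- markerLines(qcaReference(ph))
  les <- mk[mk$role == "lesion", ]
  # carve the vessel away around the lesion marker
  rc <- round((les$r0 + les$r1) / 2)
  cc <- round((les$c0 + les$c1) / 2)
  lab[(rc - 14):(rc + 16), (cc - 3):(cc + 5)] <- 0L
  holed <- SegmentationMask(lab, pixelSpacing(truthMask(ph)))
  res <- measureMarkers(holed, qcaReference(ph))
  expect_true(res$excluded)
  expect_true(res$gap_flags[["lesion"]])
  expect_match(res$reason, "gap:lesion")
  expect_true(is.na(res$stenosis_percent))
})

test_that("a reference without all vessel roles is rejected", {
  mk <- data.frame(role = c("proximal_border", "lesion"),
                   r0 = c(0, 0), c0 = c(1, 2), r1 = c(5, 5), c1 = c(1, 2))
  ref <- QcaReference(mk, 2, 0.1)
  m <- barMask(40, 40, 10, 16)
  expect_error(measureMarkers(m, ref), "invalid-reference.*distal")
})

test_that("catheter measurement: reference distance, probe chord, gap, parallelism", {
  # hand-built caliper pair 10 px apart on a 10 px catheter band
  lab <- matrix(0L, 60, 60)
  lab[, (20:29) + 1L] <- 2L
  m <- SegmentationMask(lab, 0.2)
  mk <- data.frame(
    role = c("catheter_caliper_a", "catheter_caliper_b"),
    r0 = c(10, 10), c0 = c(19.5, 29.5), r1 = c(50, 50), c1 = c(19.5, 29.5))
  ref <- QcaReference(mk, 2, 0.2, 6L)
  expect_equal(measureCatheter(NULL, ref, arm = "reference"), 10 * 0.2)
  seg <- measureCatheter(m, ref)
  expect_lt(abs(seg - 2.0), 0.2 + 1e-9)  # within 1 px * spacing
  # catheter class absent along the probe -> exclusion signal
  empty <- SegmentationMask(matrix(0L, 60, 60), 0.2)
  expect_true(is.na(measureCatheter(empty, ref)))
  # caliper lines not parallel within 2 degrees
  mk_bad <- mk
  mk_bad$c1[2] <- 34.5
  expect_error(measureCatheter(m, QcaReference(mk_bad, 2, 0.2, 6L)),
               "parallel")
})

test_that("phantom catheter measures its French diameter and round-trips the calibration", {
  tree <- defaultTreeSpec(canvas = c(320L, 320L))  # 6 Fr @ 0.1 mm/px
  ph <- generatePhantom(tree, stenosisSpec(8, 0.5, 5), seed = 2)
  ref <- qcaReference(ph)
  expect_equal(measureCatheter(NULL, ref, arm = "reference"), 2.0,
               tolerance = 1e-9)
  seg <- measureCatheter(truthMask(ph), ref)
  expect_lt(abs(seg - 2.0), 0.1 + 1e-9)  # within 1 px * spacing
  # calibration round trip from the measured catheter width
  cal <- calibrationFromCatheter(seg / calibration(ref), 6)
  expect_lt(abs(cal - 0.1) / 0.1, 0.1)
})

test_that("chord endpoints must sit inside the canvas", {
  m <- barMask(40, 40, 10, 16)
  expect_error(chordLength(m, c(-1, 20), c(30, 20)), "inside the canvas")
  expect_error(chordLength(m, c(5, 20), c(45, 20)), "inside the canvas")
})
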