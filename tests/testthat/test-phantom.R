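# Phantom generator: rasterization fidelity, analytic truth records,
# degradation defects and Dice calibration.

full_degradation <- function(seed = NULL)
  degradationSpec(boundary_jitter_sigma = 0.8, diameter_bias = -0.3,
                  collateral_gap_rate = 1, collateral_gap_length = 2,
                  catheter_gap_rate = 1, catheter_gap_length = 2.5,
                  fp_blob_rate = 2, seed = seed)

test_that("identical specs and seed give bit-identical phantoms", {
  tree <- defaultTreeSpec(canvas = c(256L, 256L))
  st <- stenosisSpec(8, 0.6, 5)
  a <- generatePhantom(tree, st, full_degradation(), seed = 42)
  b <- generatePhantom(tree, st, full_degradation(), seed = 42)
  expect_identical(maskLabels(truthMask(a)), maskLabels(truthMask(b)))
  expect_identical(maskLabels(predictedMask(a)), maskLabels(predictedMask(b)))
  expect_identical(markerLines(qcaReference(a)), markerLines(qcaReference(b)))
  expect_identical(truthRecord(a), truthRecord(b))
  # a different seed must move the degraded mask, not the truth
  c <- generatePhantom(tree, st, full_degradation(), seed = 43)
  expect_identical(maskLabels(truthMask(a)), maskLabels(truthMask(c)))
  expect_false(identical(maskLabels(predictedMask(a)),
                         maskLabels(predictedMask(c))))
})

test_that("rasterized width of a straight untapered vessel matches the analytic diameter within 1 px", {
  for (d_px in c(4, 5, 7, 8, 10, 12)) {
    tree <- straightTree(d_px * 0.1)
    ph <- generatePhantom(tree, stenosisSpec(5, 0, 4), seed = 1)
    lab <- maskLabels(truthMask(ph))
    widths <- colSums(lab[, 20:100] == 1L)  # brute-force column scan
    expect_true(all(abs(widths - d_px) <= 1),
                info = sprintf("diameter %d px", d_px))
  }
})

test_that("truth record is analytic and self-consistent", {
  # taper 0: reference = baseline; severity 0.5 on 2.0 mm -> lesion 1.0 mm
  ph <- generatePhantom(straightTree(2.0), stenosisSpec(6, 0.5, 4), seed = 1)
  rec <- truthRecord(ph)
  expect_equal(rec[["reference_mm"]], 2.0)
  expect_equal(rec[["lesion_mm"]], 1.0)
  expect_equal(rec[["stenosis_percent"]], 50)
  # severity 0: lesion equals the healthy interpolated diameter
  ph0 <- generatePhantom(straightTree(2.0, taper = 0.01),
                         stenosisSpec(5, 0, 4), seed = 1)
  rec0 <- truthRecord(ph0)
  expect_equal(rec0[["lesion_mm"]], rec0[["reference_mm"]])
  expect_equal(rec0[["stenosis_percent"]], 0)
  # conservation of the stenosis formula across random cases
  for (i in 1:12) {
    set.seed(i)
    sev <- runif(1, 0.3, 0.95)
    tree <- randomTreeSpec(i, canvas = c(320L, 320L))
    st <- stenosisSpec(runif(1, 0.3, 0.4) * mainArcLength(tree), sev, 6)
    rec <- truthRecord(generatePhantom(tree, st, seed = i))
    expect_equal(rec[["stenosis_percent"]],
                 (rec[["reference_mm"]] - rec[["lesion_mm"]]) /
                   rec[["reference_mm"]] * 100, tolerance = 1e-12)
    expect_equal(rec[["stenosis_percent"]], sev * 100, tolerance = 1e-9)
  }
})

test_that("invalid geometry is rejected with invalid-spec errors", {
  # tube pushed over the canvas edge
  tree <- vesselTreeSpec(c(96, 128), 0.1,
                         rbind(c(4, 16), c(4, 111)), 2.0)
  expect_error(generatePhantom(tree, stenosisSpec(5, 0.5, 4), seed = 1),
               "leaves the canvas")
  # marker line exits the canvas (vessel fits, markers do not)
  tree2 <- vesselTreeSpec(c(96, 128), 0.1,
                          rbind(c(20, 16), c(20, 111)), 2.0)
  expect_error(generatePhantom(tree2, stenosisSpec(5, 0.5, 4), seed = 1),
               "marker line exits")
  # stenosis window outside the arc
  expect_error(generatePhantom(straightTree(2.0), stenosisSpec(9.2, 0.5, 4),
                               seed = 1),
               "inside the vessel arc")
})

test_that("near-resolution lesions are flagged, not silently produced", {
  ph <- generatePhantom(straightTree(2.0), stenosisSpec(6, 0.95, 4),
                        seed = 1)
  expect_true("resolution-limit" %in% ph@provenance$warnings)
})

test_that("zero-defect degradation is the identity", {
  tree <- defaultTreeSpec(canvas = c(256L, 256L))
  ph <- generatePhantom(tree, stenosisSpec(8, 0.6, 5),
                        degradationSpec(), seed = 9)
  expect_identical(maskLabels(predictedMask(ph)), maskLabels(truthMask(ph)))
})

test_that("a forced collateral gap removes one distal run of branch pixels", {
  tree <- defaultTreeSpec(canvas = c(320L, 320L))
  tree$branches <- tree$branches[1]
  ph <- generatePhantom(tree, stenosisSpec(8, 0.5, 5), seed = 3)
  spec <- degradationSpec(collateral_gap_rate = 1, collateral_gap_length = 2)
  pred <- degradeMask(truthMask(ph), spec, geometry = ph@geometry, seed = 3)
  tru <- maskLabels(truthMask(ph)); new <- maskLabels(pred)
  expect_gt(sum(tru == 1L) - sum(new == 1L), 0)
  # walk the branch centerline: its class sequence must show exactly one
  # zeroed run, located in the distal half
  g <- ph@geometry$branches[[1]]
  idx <- cbind(round(g$row) + 1L, round(g$col) + 1L)
  on_branch <- new[idx] == 1L
  was_branch <- tru[idx] == 1L
  runs <- rle(on_branch[was_branch])
  expect_identical(sum(!runs$values), 1L)
  gap_s <- g$s_mm[was_branch][!on_branch[was_branch]]
  expect_true(all(gap_s > g$arc_mm / 2))
  # extent = configured length plus the stamp bleed (local radius + 1.5 px
  # at each end)
  bleed <- 2 * (max(g$diam_mm) / 2 + 1.5 * 0.1)
  expect_lt(max(gap_s) - min(gap_s), spec$collateral_gap_length + bleed + 0.5)
})

test_that("a forced catheter gap erases catheter pixels near the tip", {
  tree <- defaultTreeSpec(canvas = c(320L, 320L))
  ph <- generatePhantom(tree, stenosisSpec(8, 0.5, 5), seed = 4)
  spec <- degradationSpec(catheter_gap_rate = 1, catheter_gap_length = 2.5)
  pred <- degradeMask(truthMask(ph), spec, geometry = ph@geometry, seed = 4)
  tru <- maskLabels(truthMask(ph)); new <- maskLabels(pred)
  expect_gt(sum(tru == 2L) - sum(new == 2L), 0)
  expect_identical(sum(tru == 1L), sum(new == 1L))  # coronary untouched
})

test_that("false-positive blobs land off-vessel and create FP pixels", {
  tree <- defaultTreeSpec(canvas = c(320L, 320L))
  ph <- generatePhantom(tree, stenosisSpec(8, 0.5, 5), seed = 5)
  pred <- degradeMask(truthMask(ph), degradationSpec(fp_blob_rate = 3),
                      geometry = ph@geometry, seed = 5)
  cnt <- classifyPixels(truthMask(ph), pred)
  expect_gt(cnt@fp, 0)
  expect_identical(cnt@fn, 0)
  # blob pixels must not touch the true foreground
  tru <- maskLabels(truthMask(ph)); new <- maskLabels(pred)
  blob <- which(new == 1L & tru == 0L, arr.ind = TRUE)
  fg <- which(tru != 0L, arr.ind = TRUE)
  dmin <- min(sqrt(outer(blob[, 1], fg[, 1], "-")^2 +
                     outer(blob[, 2], fg[, 2], "-")^2))
  expect_gt(dmin, 1.5)
})

test_that("gap defects without geometry are skipped with a warning", {
  m <- barMask(96, 96, 40, 50)
  expect_warning(degradeMask(m, degradationSpec(collateral_gap_rate = 1,
                                                collateral_gap_length = 2),
                             seed = 1),
                 "geometry")
})

test_that("realized Dice decreases with boundary jitter (20-seed average)", {
  tree <- defaultTreeSpec(canvas = c(256L, 256L))
  ph <- generatePhantom(tree, stenosisSpec(8, 0.5, 5), seed = 1)
  tm <- truthMask(ph)
  mean_dice <- vapply(c(0.5, 1, 2, 4), function(sg) {
    mean(vapply(1:20, function(s) {
      p <- degradeMask(tm, degradationSpec(boundary_jitter_sigma = sg),
                       seed = s)
      cnt <- classifyPixels(tm, p)
      2 * cnt@tp / (2 * cnt@tp + cnt@fn + cnt@fp)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) < 0))
})

test_that("calibrateToDice honours its contract", {
  tree <- defaultTreeSpec(canvas = c(256L, 256L))
  ph <- generatePhantom(tree, stenosisSpec(8, 0.5, 5), seed = 1)
  tm <- truthMask(ph)
  # target 1 with a zero-defect template: the identity spec, Dice 1
  cal <- calibrateToDice(tm, 1.0, seed = 7)
  expect_identical(cal$spec$boundary_jitter_sigma, 0)
  expect_identical(cal$realized, 1)
  # out-of-range target
  expect_error(calibrateToDice(tm, 0.4, seed = 7), "\\(0.5, 1\\]")
  # unreachable: perfection demanded of a template with mandatory gaps
  tmpl <- degradationSpec(collateral_gap_rate = 1, collateral_gap_length = 3)
  expect_error(calibrateToDice(tm, 1.0, template = tmpl, seed = 7,
                               geometry = ph@geometry),
               "unreachable.*realized")
  # a standard target converges within tolerance
  cal2 <- calibrateToDice(tm, 0.95, seed = 7)
  expect_lte(abs(cal2$realized - 0.95), 0.02)
})
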