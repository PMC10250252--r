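# Pipeline module: orchestrate the full synthetic validation study --
# generate N phantom cases, degrade, measure both arms, compute overlap and
# statistics, and emit a report with a reproducibility manifest.

#' Study configuration
#'
#' Defines the cohort the synthetic study is generated under. Defaults
#' mirror a multicentric QCA validation cohort: lesion severity strata with
#' fractions 0.18 / 0.47 / 0.35 for >=70\%, 50--69\% and <50\% stenoses,
#' 512 x 512 masks at 0.1 mm/px, and a degradation calibrated to a target
#' whole-image Dice of 0.95.
#'
#' @param n_cases number of phantom cases to generate (>= 1).
#' @param canvas integer(2) canvas size in pixels.
#' @param spacing pixel spacing, mm/px.
#' @param severity_strata data.frame with columns \code{stratum},
#'   \code{min}, \code{max}, \code{fraction}; fractions must sum to 1.
#' @param target_dice whole-image coronary Dice the degradation is
#'   calibrated to (on the first case), or NULL to use \code{degradation}
#'   as-is.
#' @param degradation a \code{\link{degradationSpec}} template; NULL uses
#'   the package default defect profile (slight under-segmentation bias,
#'   frequent distal collateral gaps, catheter gaps near the tip, occasional
#'   false-positive blobs).
#' @param lesion_position numeric(2), lesion centre position as a fraction
#'   of the main arc length (sampled uniformly).
#' @param lesion_length lesion length in mm.
#' @param n_branches side branches per phantom.
#' @param roi_padding ROI padding around the marker bounding box, pixels.
#' @param seed root RNG seed for the whole study.
#' @return A validated list of class \code{StudyConfig}.
#' @export
studyConfig <- function(n_cases = 120L, canvas = c(512L, 512L),
                        spacing = 0.1,
                        severity_strata = data.frame(
                          stratum = c(">=70%", "50-69%", "<50%"),
                          min = c(0.70, 0.50, 0.30),
                          max = c(0.95, 0.69, 0.49),
                          fraction = c(0.18, 0.47, 0.35)),
                        target_dice = 0.95, degradation = NULL,
                        lesion_position = c(0.28, 0.42), lesion_length = 8,
                        n_branches = 2L, roi_padding = 10L, seed = 1L) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 1L) .stopf("config error: n_cases must be >= 1")
  if (!is.data.frame(severity_strata) ||
      !all(c("min", "max", "fraction") %in% names(severity_strata)))
    .stopf("config error: severity_strata needs columns min, max, fraction")
  if (abs(sum(severity_strata$fraction) - 1) > 1e-6)
    .stopf("config error: severity stratum fractions must sum to 1")
  if (is.null(severity_strata$stratum))
    severity_strata$stratum <- sprintf("stratum%d",
                                       seq_len(nrow(severity_strata)))
  if (!is.null(target_dice) &&
      !(target_dice > 0.5 && target_dice <= 1))
    .stopf("config error: target_dice must lie in (0.5, 1]")
  if (is.null(degradation))
    degradation <- degradationSpec(diameter_bias = -0.3,
                                   collateral_gap_rate = 0.6,
                                   collateral_gap_length = 2,
                                   catheter_gap_rate = 0.5,
                                   catheter_gap_length = 2.5,
                                   fp_blob_rate = 1, fp_blob_diameter = 6)
  stopifnot(inherits(degradation, "DegradationSpec"))
  structure(list(n_cases = n_cases, canvas = as.integer(canvas),
                 spacing = spacing, severity_strata = severity_strata,
                 target_dice = target_dice, degradation = degradation,
                 lesion_position = lesion_position,
                 lesion_length = lesion_length,
                 n_branches = as.integer(n_branches),
                 roi_padding = as.integer(roi_padding),
                 seed = as.integer(seed)),
            class = "StudyConfig")
}

.TABLE3_PARAMS <- data.frame(
  key = c("stenosis", "lesion", "proximal", "distal"),
  label = c("Diameter Stenosis (%)", "Diameter at lesion (mm)",
            "Diameter at proximal obstruction border (mm)",
            "Diameter at distal obstruction border (mm)"),
  orig = c("orig_stenosis", "orig_lesion_mm", "orig_proximal_mm",
           "orig_distal_mm"),
  seg = c("seg_stenosis", "seg_lesion_mm", "seg_proximal_mm",
          "seg_distal_mm"))

#' Run the full synthetic validation study
#'
#' For each case: generate a randomized phantom (truth + QCA reference),
#' degrade it into a simulated prediction, measure the markers on the
#' prediction (the "segmented image" arm) against the analytic truth
#' diameters (the "original image" arm, playing the validated-software
#' role), compute overlap counts and metrics in the marker ROI and over the
#' whole image, and accumulate. Cases whose vessel markers hit a
#' segmentation gap are excluded from statistics with an explicit reason;
#' stage errors are recorded per case and never abort the study. Fully
#' deterministic under a fixed config seed.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param cases_dir optional directory; when given, every case's masks and
#'   sidecar are written there as they are generated.
#' @param verbose print per-case progress.
#' @return A \linkS4class{StudyResult}.
#' @export
runStudy <- function(config, cases_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "StudyConfig"))
  deg <- config$degradation
  calib <- list(target = config$target_dice, realized = NA_real_,
                sigma = deg$boundary_jitter_sigma)
  if (!is.null(config$target_dice)) {
    tree1 <- randomTreeSpec(.subSeed(config$seed, 1001L), config$canvas,
                            config$spacing, config$n_branches)
    st1 <- .sampleStenosis(config, .subSeed(config$seed, 1001L), tree1)
    ph1 <- generatePhantom(tree1, st1$spec, degradationSpec(),
                           seed = .subSeed(config$seed, 1001L))
    cal <- calibrateToDice(ph1@truth, config$target_dice, template = deg,
                           seed = .subSeed(config$seed, 500L),
                           geometry = ph1@geometry)
    deg <- cal$spec
    calib$realized <- cal$realized
    calib$sigma <- deg$boundary_jitter_sigma
  }

  rows <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    case_seed <- .subSeed(config$seed, 1000L + i)
    rows[[i]] <- .runCase(i, case_seed, config, deg, cases_dir)
    if (verbose)
      message(sprintf("case %03d: %s", i,
                      if (rows[[i]]$excluded) rows[[i]]$reason else "ok"))
  }
  cases <- do.call(rbind, rows)
  included <- cases[!cases$excluded, , drop = FALSE]

  comparisons <- list()
  if (nrow(included) >= 3L) {
    for (j in seq_len(nrow(.TABLE3_PARAMS))) {
      p <- .TABLE3_PARAMS[j, ]
      comparisons[[p$key]] <- pairedCompare(included[[p$orig]],
                                            included[[p$seg]],
                                            parameter = p$label,
                                            units = if (p$key == "stenosis")
                                              "%" else "mm")
    }
    for (fr in c(5L, 6L)) {
      sub <- included[!included$cath_excluded &
                        included$cath_french == fr, , drop = FALSE]
      if (nrow(sub) >= 3L)
        comparisons[[sprintf("catheter_%dfr", fr)]] <-
          pairedCompare(sub$cath_ref_mm, sub$cath_seg_mm,
                        parameter = sprintf("Catheter diameter, %d Fr (mm)", fr),
                        units = "mm")
    }
    if (length(unique(included$stratum)) >= 2L &&
        all(table(included$stratum) >= 2L))
      comparisons$dice_by_severity <-
        groupCompare(included$dice, included$stratum,
                     parameter = "Dice (%) by severity stratum")
  }

  metric_cols <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                   "iou", "dice")
  overlapSummary <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- included[[mc]]
    if (!length(v) || all(is.na(v)))
      return(data.frame(metric = mc, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_))
    q <- medianIqr(v)
    data.frame(metric = mc, median = q[["median"]], q25 = q[["q25"]],
               q75 = q[["q75"]])
  }))

  reasons <- table(cases$reason[cases$excluded])
  manifest <- list(
    seed = config$seed,
    config_hash = .objectHash(unclass(config)),
    package_version = as.character(utils::packageVersion("phantomQCA")),
    schema_version = .SCHEMA_VERSION,
    n_generated = nrow(cases),
    n_included = nrow(included),
    n_excluded = sum(cases$excluded),
    exclusion_reasons = as.list(reasons),
    stats_case_ids = included$case_id,
    calibration = calib)

  new("StudyResult", cases = cases, comparisons = comparisons,
      overlapSummary = overlapSummary, manifest = manifest,
      config = unclass(config))
}

.sampleStenosis <- function(config, seed, tree) {
  set.seed(.subSeed(seed, 77L))
  st <- config$severity_strata
  k <- sample.int(nrow(st), 1, prob = st$fraction)
  sev <- stats::runif(1, st$min[k], st$max[k])
  arc <- mainArcLength(tree)
  pos <- stats::runif(1, config$lesion_position[1],
                      config$lesion_position[2]) * arc
  list(spec = stenosisSpec(pos, sev, config$lesion_length),
       stratum = as.character(st$stratum[k]))
}

.naCaseRow <- function(i, case_seed, reason) {
  data.frame(case_id = i, seed = case_seed, stratum = NA_character_,
             severity_true = NA_real_, arc_mm = NA_real_,
             lesion_pos_mm = NA_real_,
             orig_stenosis = NA_real_, orig_lesion_mm = NA_real_,
             orig_proximal_mm = NA_real_, orig_distal_mm = NA_real_,
             orig_reference_mm = NA_real_,
             tru_stenosis = NA_real_, tru_lesion_mm = NA_real_,
             tru_proximal_mm = NA_real_, tru_distal_mm = NA_real_,
             seg_stenosis = NA_real_, seg_lesion_mm = NA_real_,
             seg_proximal_mm = NA_real_, seg_distal_mm = NA_real_,
             cath_french = NA_integer_, cath_ref_mm = NA_real_,
             cath_seg_mm = NA_real_, cath_excluded = TRUE,
             cath_reason = "not-measured",
             tp = NA_real_, fp = NA_real_, tn = NA_real_, fn = NA_real_,
             roi_area = NA_real_, accuracy = NA_real_,
             sensitivity = NA_real_, specificity = NA_real_,
             ppv = NA_real_, npv = NA_real_, iou = NA_real_,
             dice = NA_real_, iou_whole = NA_real_, dice_whole = NA_real_,
             warn_resolution = FALSE, excluded = TRUE, reason = reason,
             stringsAsFactors = FALSE)
}

.runCase <- function(i, case_seed, config, deg, cases_dir) {
  ph <- tryCatch({
    tree <- randomTreeSpec(case_seed, config$canvas, config$spacing,
                           config$n_branches)
    sten <- .sampleStenosis(config, case_seed, tree)
    ph <- generatePhantom(tree, sten$spec, deg, seed = case_seed)
    ph@provenance$stratum <- sten$stratum
    ph
  }, error = function(e) e)
  if (inherits(ph, "error"))
    return(.naCaseRow(i, case_seed, paste0("generation-error: ",
                                           conditionMessage(ph))))

  if (!is.null(cases_dir))
    writeCase(ph, cases_dir, sprintf("case_%03d", i))

  ref <- ph@reference
  rec <- ph@truthRecord
  mt <- measureMarkers(ph@truth, ref)
  mp <- measureMarkers(ph@predicted, ref)
  cath_ref <- measureCatheter(NULL, ref, arm = "reference")
  cath_seg <- measureCatheter(ph@predicted, ref, arm = "segmented")

  roi <- roiFromMarkers(ref, dim(ph@truth), padding = config$roi_padding)
  met <- suppressWarnings(
    overlapMetrics(classifyPixels(ph@truth, ph@predicted, roi)))
  whole <- suppressWarnings(
    overlapMetrics(classifyPixels(ph@truth, ph@predicted)))
  md <- as.data.frame(met)

  data.frame(case_id = i, seed = case_seed,
             stratum = ph@provenance$stratum,
             severity_true = ph@provenance$stenosis$severity,
             arc_mm = ph@geometry$main$arc_mm,
             lesion_pos_mm = ph@provenance$stenosis$position_mm,
             orig_stenosis = rec[["stenosis_percent"]],
             orig_lesion_mm = rec[["lesion_mm"]],
             orig_proximal_mm = rec[["proximal_mm"]],
             orig_distal_mm = rec[["distal_mm"]],
             orig_reference_mm = rec[["reference_mm"]],
             tru_stenosis = mt$stenosis_percent,
             tru_lesion_mm = mt$lesion_mm,
             tru_proximal_mm = mt$proximal_mm,
             tru_distal_mm = mt$distal_mm,
             seg_stenosis = mp$stenosis_percent,
             seg_lesion_mm = mp$lesion_mm,
             seg_proximal_mm = mp$proximal_mm,
             seg_distal_mm = mp$distal_mm,
             cath_french = ref@catheterFrench,
             cath_ref_mm = cath_ref,
             cath_seg_mm = cath_seg,
             cath_excluded = is.na(cath_seg),
             cath_reason = if (is.na(cath_seg)) "gap:catheter" else "",
             tp = md$tp, fp = md$fp, tn = md$tn, fn = md$fn,
             roi_area = (roi$row_max - roi$row_min) *
               (roi$col_max - roi$col_min),
             accuracy = md$accuracy, sensitivity = md$sensitivity,
             specificity = md$specificity, ppv = md$ppv, npv = md$npv,
             iou = md$iou, dice = md$dice,
             iou_whole = 100 * whole@iou, dice_whole = 100 * whole@dice,
             warn_resolution = "resolution-limit" %in%
               ph@provenance$warnings,
             excluded = mp$excluded,
             reason = mp$reason,
             stringsAsFactors = FALSE)
}

#' Audit a study result
#'
#' Verifies the reconciliation invariants a reader of the study flowchart
#' relies on: generated = included + excluded with per-reason counts;
#' excluded cases never contribute to the statistics sample; per-case
#' confusion counts fill the ROI exactly; and per-case Dice equals
#' 2*IoU/(1+IoU).
#'
#' @param result a \linkS4class{StudyResult}.
#' @return list of class \code{studyAudit} with \code{pass} and a character
#'   vector of \code{violations} (empty when clean).
#' @export
auditStudy <- function(result) {
  stopifnot(is(result, "StudyResult"))
  cs <- result@cases
  m <- result@manifest
  v <- character()
  if (m$n_included + m$n_excluded != m$n_generated)
    v <- c(v, "flowchart: included + excluded != generated")
  if (sum(cs$excluded) != m$n_excluded)
    v <- c(v, "flowchart: excluded flag count disagrees with the manifest")
  n_reason <- sum(unlist(m$exclusion_reasons))
  if (n_reason != m$n_excluded)
    v <- c(v, "flowchart: per-reason counts do not sum to n_excluded")
  leak <- intersect(m$stats_case_ids, cs$case_id[cs$excluded])
  if (length(leak))
    v <- c(v, sprintf("exclusion leak: excluded case(s) %s present in the statistics sample",
                      paste(leak, collapse = ", ")))
  if (length(m$stats_case_ids) != m$n_included)
    v <- c(v, "statistics sample size disagrees with n_included")
  ok <- !cs$excluded
  if (any(ok)) {
    iou <- cs$iou[ok] / 100
    implied <- 100 * diceFromIoU(iou)
    bad <- which(abs(implied - cs$dice[ok]) > 1e-9)
    if (length(bad))
      v <- c(v, sprintf("Dice != 2*IoU/(1+IoU) for case(s) %s",
                        paste(cs$case_id[ok][bad], collapse = ", ")))
    counts_sum <- cs$tp[ok] + cs$fp[ok] + cs$tn[ok] + cs$fn[ok]
    bad2 <- which(counts_sum != cs$roi_area[ok])
    if (length(bad2))
      v <- c(v, sprintf("confusion counts do not fill the ROI for case(s) %s",
                        paste(cs$case_id[ok][bad2], collapse = ", ")))
  }
  structure(list(pass = length(v) == 0L, violations = v),
            class = "studyAudit")
}

#' @export
print.studyAudit <- function(x, ...) {
  if (x$pass) cat("study audit: PASS\n")
  else cat("study audit: FAIL\n -", paste(x$violations, collapse = "\n - "),
           "\n")
  invisible(x)
}

.fmtMeanSd <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
.fmtMedIqr <- function(q) sprintf("%.1f (%.1f–%.1f)", q[1], q[2], q[3])

#' Write the study report to disk
#'
#' Emits \code{measurements.csv} (one row per case: both arms, flags),
#' \code{overlap.csv} (metric columns plus raw counts), \code{report.md}
#' (flowchart reconciliation, severity distribution, detailed-measurement,
#' median-difference and overlap tables, catheter sub-study, optional GSS),
#' and \code{manifest.json}. Output is deterministic: the same study result
#' always produces byte-identical files.
#'
#' @param result a \linkS4class{StudyResult}.
#' @param dir output directory, created if needed.
#' @param gss optional \code{GssSummary} merged into the report.
#' @return \code{dir}, invisibly.
#' @export
writeStudyReport <- function(result, dir, gss = NULL) {
  stopifnot(is(result, "StudyResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- result@cases
  meas_cols <- c("case_id", "seed", "stratum", "severity_true",
                 grep("^(orig|tru|seg|cath)_", names(cs), value = TRUE),
                 "warn_resolution", "excluded", "reason")
  utils::write.csv(cs[, meas_cols], file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  ov_cols <- c("case_id", "accuracy", "sensitivity", "specificity", "ppv",
               "npv", "iou", "dice", "iou_whole", "dice_whole", "tp", "fp",
               "tn", "fn", "roi_area", "excluded")
  utils::write.csv(cs[, ov_cols], file.path(dir, "overlap.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  inc <- cs[!cs$excluded, , drop = FALSE]
  m <- result@manifest
  L <- c("# Synthetic segmentation validation study", "",
         "## Case flowchart", "",
         sprintf("- generated: %d", m$n_generated),
         sprintf("- included: %d", m$n_included),
         sprintf("- excluded: %d", m$n_excluded))
  for (r in names(m$exclusion_reasons))
    L <- c(L, sprintf("    - %s: %d", r, m$exclusion_reasons[[r]]))
  L <- c(L, "", "## Lesion severity distribution", "",
         "| Stratum | N (%) |", "| --- | --- |")
  st <- result@config$severity_strata
  for (k in seq_len(nrow(st))) {
    n_k <- sum(inc$stratum == st$stratum[k], na.rm = TRUE)
    L <- c(L, sprintf("| %s | %s |", st$stratum[k],
                      countPercent(n_k, max(1L, nrow(inc)))$label))
  }
  L <- c(L, "", "## Detailed measurements (mean ± SD)", "",
         "| Parameter | Original Image | Segmented Image | P-value |",
         "| --- | --- | --- | --- |")
  for (j in seq_len(nrow(.TABLE3_PARAMS))) {
    p <- .TABLE3_PARAMS[j, ]
    cmp <- result@comparisons[[p$key]]
    pv <- if (is.null(cmp)) "-" else sprintf("%.3f%s", cmp$p_value,
                                             if (cmp$significant) " *" else "")
    L <- c(L, sprintf("| %s | %s | %s | %s |", p$label,
                      .fmtMeanSd(inc[[p$orig]]), .fmtMeanSd(inc[[p$seg]]),
                      pv))
  }
  L <- c(L, "", "## Median absolute differences (median, IQ 25th–75th)",
         "", "| Parameter | Difference |", "| --- | --- |")
  for (j in seq_len(nrow(.TABLE3_PARAMS))) {
    p <- .TABLE3_PARAMS[j, ]
    q <- medianIqr(abs(inc[[p$orig]] - inc[[p$seg]]))
    L <- c(L, sprintf("| %s | %s |", p$label,
                      sprintf("%.2f (%.2f–%.2f)", q[1], q[2], q[3])))
  }
  os <- result@overlapSummary
  hdr <- c(accuracy = "Accuracy (%)", sensitivity = "Sensitivity (%)",
           specificity = "Specificity (%)",
           ppv = "Positive predictive value (%)",
           npv = "Negative predictive value (%)",
           iou = "Intersection over Union (%)", dice = "Dice Score (%)")
  L <- c(L, "", "## Overlap metrics (median, IQ 25th–75th)", "",
         paste0("| ", paste(hdr[os$metric], collapse = " | "), " |"),
         paste0("|", paste(rep(" --- ", nrow(os)), collapse = "|"), "|"),
         paste0("| ", paste(sprintf("%.1f (%.1f–%.1f)", os$median,
                                    os$q25, os$q75), collapse = " | "),
                " |"))
  cath <- result@comparisons[grep("^catheter_", names(result@comparisons))]
  if (length(cath)) {
    L <- c(L, "", "## Catheter diameters", "",
           "| Parameter | Original Image | Segmented Image | P-value | n |",
           "| --- | --- | --- | --- | --- |")
    for (cmp in cath)
      L <- c(L, sprintf("| %s | %.2f ± %.2f | %.2f ± %.2f | %.3f | %d |",
                        cmp$parameter, cmp$original$mean, cmp$original$sd,
                        cmp$segmented$mean, cmp$segmented$sd, cmp$p_value,
                        cmp$n))
    n_cath_exc <- sum(cs$cath_excluded)
    L <- c(L, "",
           sprintf("Catheter sub-study exclusions: %s of %d cases.",
                   countPercent(n_cath_exc, nrow(cs))$label, nrow(cs)))
  }
  if (!is.null(gss)) {
    L <- c(L, "", "## Global Segmentation Score", "",
           sprintf("GSS %s (%s–%s); n scored %d, n excluded %d.",
                   format(gss$median), format(gss$q25), format(gss$q75),
                   gss$n_scored, gss$n_excluded))
  }
  L <- c(L, "", "## Manifest", "",
         sprintf("- seed: %d", m$seed),
         sprintf("- config hash: %s", m$config_hash),
         sprintf("- calibration: target %s, realized %s (sigma %.3f)",
                 format(m$calibration$target %||% "none"),
                 format(round(m$calibration$realized, 4)),
                 m$calibration$sigma),
         sprintf("- package version: %s", m$package_version))
  writeLines(L, file.path(dir, "report.md"))
  invisible(dir)
}
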