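# IO: masks as 8-bit grayscale PNG (0 background, 255 coronary,
# 128 catheter -- lossless and diff-friendly), references and case sidecars
# as versioned JSON, study configs as YAML/JSON.

.SCHEMA_VERSION <- "1.0"
.PNG_VALUES <- c(0, 255, 128) / 255  # indexed by label + 1

#' Write a segmentation mask to PNG
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param path output path (single-channel 8-bit PNG). Pixel spacing is not
#'   stored in the PNG; it travels in the JSON sidecar.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SegmentationMask"))
  img <- matrix(.PNG_VALUES[mask@labels + 1L], nrow(mask@labels))
  png::writePNG(img, path)
  invisible(path)
}

#' Read a segmentation mask from PNG
#'
#' @param path PNG path written by \code{\link{writeMask}} (or any 8-bit
#'   grayscale mask using the 0/255/128 encoding).
#' @param spacing pixel spacing in mm/pixel (from the case sidecar).
#' @return A \linkS4class{SegmentationMask}.
#' @export
readMask <- function(path, spacing) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  v <- round(img * 255)
  lab <- matrix(0L, nrow(v), ncol(v))
  lab[v == 255] <- 1L
  lab[v == 128] <- 2L
  if (!all(v %in% c(0, 128, 255)))
    .stopf("mask PNG contains values outside the 0/128/255 encoding")
  SegmentationMask(lab, spacing)
}

.refToList <- function(ref) {
  list(markers = ref@markers,
       reference_diameter = ref@referenceDiameter,
       calibration = ref@calibration,
       catheter_french = if (is.na(ref@catheterFrench)) NULL else
         ref@catheterFrench)
}

.refFromList <- function(x) {
  QcaReference(as.data.frame(x$markers),
               reference_diameter = x$reference_diameter,
               calibration = x$calibration,
               catheter_french = x$catheter_french %||% NA_integer_)
}

#' Write a phantom case to disk
#'
#' Emits \code{<stem>_truth.png}, \code{<stem>_pred.png} and
#' \code{<stem>.json} (QCA reference, analytic truth record, generating
#' specs and seed; schema versioned).
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param dir output directory (created if needed).
#' @param stem filename stem, e.g. \code{"case_001"}.
#' @return The sidecar path, invisibly.
#' @export
writeCase <- function(case, dir, stem) {
  stopifnot(is(case, "PhantomCase"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMask(case@truth, file.path(dir, paste0(stem, "_truth.png")))
  writeMask(case@predicted, file.path(dir, paste0(stem, "_pred.png")))
  pv <- case@provenance
  doc <- list(schema_version = .SCHEMA_VERSION,
              spacing = case@truth@spacing,
              seed = pv$seed,
              reference = .refToList(case@reference),
              truth_record = as.list(case@truthRecord),
              warnings = pv$warnings,
              specs = list(
                tree = .treeToList(pv$tree),
                stenosis = unclass(pv$stenosis),
                degradation = unclass(pv$degradation)))
  path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.treeToList <- function(tree) {
  list(canvas = tree$canvas, spacing = tree$spacing,
       centerline = tree$centerline,
       baseline_diameter = tree$baseline_diameter,
       taper_rate = tree$taper_rate,
       branches = lapply(tree$branches, unclass),
       catheter = if (is.null(tree$catheter)) NULL else
         list(french_size = tree$catheter$french_size,
              centerline = tree$catheter$centerline))
}

#' Read a case sidecar back
#'
#' @param path the \code{<stem>.json} sidecar written by
#'   \code{\link{writeCase}}.
#' @return list with \code{reference} (\linkS4class{QcaReference}),
#'   \code{truth_record}, \code{spacing}, \code{seed}, \code{warnings} and
#'   the mask paths implied by the stem.
#' @export
readCaseSidecar <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stem <- sub("\\.json$", "", path)
  list(reference = .refFromList(doc$reference),
       truth_record = unlist(doc$truth_record),
       spacing = doc$spacing, seed = doc$seed,
       warnings = doc$warnings,
       truth_png = paste0(stem, "_truth.png"),
       pred_png = paste0(stem, "_pred.png"))
}

#' Read a study configuration from YAML or JSON
#'
#' Fields mirror \code{\link{studyConfig}} arguments field-for-field;
#' unknown fields are rejected.
#'
#' @param path path to a .yaml/.yml or .json config file.
#' @return A validated \code{StudyConfig}.
#' @export
readStudyConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(studyConfig))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    .stopf("config error: unknown field(s): %s", paste(extra, collapse = ", "))
  if (!is.null(cfg$severity_strata))
    cfg$severity_strata <- as.data.frame(cfg$severity_strata)
  if (!is.null(cfg$degradation))
    cfg$degradation <- do.call(degradationSpec, cfg$degradation)
  do.call(studyConfig, cfg)
}
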