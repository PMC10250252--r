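# GSS module: the Global Segmentation Score rubric (0-100 points awarded by
# expert consensus), per-image assessments, and study-level aggregation.
# The rating itself is human work; this module represents and aggregates it.

#' Build and validate a GSS rubric
#'
#' A rubric is an ordered list of criteria whose maximum points sum to
#' exactly 100. Criteria flagged \code{catheter} are unscorable on images
#' where collimation hides the catheter.
#'
#' @param criteria data.frame with columns \code{id}, \code{description},
#'   \code{max_points} and optionally \code{catheter} (logical, default
#'   FALSE).
#' @param version free-form version tag.
#' @return A validated list of class \code{GssRubric}.
#' @export
gssRubric <- function(criteria, version = "1") {
  if (!is.data.frame(criteria) || !nrow(criteria))
    .stopf("invalid-rubric: criteria must be a non-empty data.frame")
  need <- c("id", "description", "max_points")
  if (!all(need %in% names(criteria)))
    .stopf("invalid-rubric: criteria need columns id, description, max_points")
  if (is.null(criteria$catheter)) criteria$catheter <- FALSE
  if (anyDuplicated(criteria$id))
    .stopf("invalid-rubric: criterion ids must be unique")
  if (any(criteria$max_points <= 0))
    .stopf("invalid-rubric: max_points must all be > 0")
  if (sum(criteria$max_points) != 100)
    .stopf("invalid-rubric: max_points must sum to exactly 100 (got %s)",
           sum(criteria$max_points))
  structure(list(criteria = criteria, version = as.character(version)),
            class = "GssRubric")
}

#' Validate an existing rubric object
#'
#' @param rubric a \code{GssRubric} or a bare criteria data.frame.
#' @return The validated \code{GssRubric} (errors otherwise).
#' @export
validateRubric <- function(rubric) {
  if (inherits(rubric, "GssRubric"))
    return(gssRubric(rubric$criteria, rubric$version))
  gssRubric(rubric)
}

#' A default example rubric
#'
#' Ships with criteria reflecting the qualities expert raters look at in a
#' coronary segmentation (main-vessel completeness, collateral continuity,
#' catheter continuity, artifact burden). The point allocation is a
#' placeholder, not a published weighting: replace it with your own rubric
#' for any real rating exercise.
#'
#' @return A \code{GssRubric}.
#' @export
defaultGssRubric <- function() {
  gssRubric(data.frame(
    id = c("main_vessel", "collaterals", "catheter", "artifacts"),
    description = c(
      "Main vessel completeness and border fidelity",
      "Continuity of small collaterals (distal gaps penalized)",
      "Catheter continuity, including the tip region",
      "Freedom from false-positive artifacts"),
    max_points = c(45, 25, 20, 10),
    catheter = c(FALSE, FALSE, TRUE, FALSE)),
    version = "example-1")
}

#' Record one GSS assessment
#'
#' @param case_id case identifier.
#' @param points named numeric vector of awarded points, one per criterion
#'   id; catheter criteria may be NA when \code{catheter_scorable} is FALSE.
#' @param rubric the \code{GssRubric} scored against.
#' @param rater rater id, or \code{"consensus"} (consensus is a single
#'   assessment row, not derived from rater rows).
#' @param catheter_scorable FALSE when collimation precludes scoring the
#'   catheter criteria.
#' @return list of class \code{GssAssessment} with the awarded points and
#'   total.
#' @export
gssAssessment <- function(case_id, points, rubric, rater = "consensus",
                          catheter_scorable = TRUE) {
  rubric <- validateRubric(rubric)
  cr <- rubric$criteria
  if (!all(cr$id %in% names(points)))
    .stopf("points must name every rubric criterion")
  pts <- points[cr$id]
  na_ok <- !catheter_scorable & cr$catheter
  if (any(is.na(pts) & !na_ok))
    .stopf("NA points are only allowed for catheter criteria of catheter-unscorable cases")
  bad <- !is.na(pts) & (pts < 0 | pts > cr$max_points)
  if (any(bad))
    .stopf("awarded points must lie in [0, max] for criterion %s",
           paste(cr$id[bad], collapse = ", "))
  structure(list(case_id = case_id, points = pts,
                 total = sum(pts, na.rm = TRUE), rater = rater,
                 catheter_scorable = isTRUE(catheter_scorable)),
            class = "GssAssessment")
}

#' Summarize GSS assessments
#'
#' Median and interquartile range of totals over fully scorable cases
#' (type-6 quantiles, the convention of clinical statistics software), plus
#' per-criterion medians. Catheter-unscorable cases (collimation) are
#' excluded from totals and from catheter-criterion summaries, but still
#' contribute to the other criteria.
#'
#' @param assessments list of \code{GssAssessment}.
#' @param rubric the \code{GssRubric} the assessments were scored against.
#' @return list of class \code{GssSummary}: \code{median}, \code{q25},
#'   \code{q75}, \code{per_criterion} (data.frame id/median/n),
#'   \code{n_scored}, \code{n_excluded}.
#' @export
summarizeGss <- function(assessments, rubric) {
  rubric <- validateRubric(rubric)
  if (!length(assessments))
    .stopf("empty-input: at least one assessment is required")
  stopifnot(all(vapply(assessments, inherits, logical(1), "GssAssessment")))
  scorable <- vapply(assessments, function(a) a$catheter_scorable, logical(1))
  if (!any(scorable))
    .stopf("empty-input: no fully scorable assessments")
  totals <- vapply(assessments[scorable], function(a) a$total, numeric(1))
  cr <- rubric$criteria
  per <- do.call(rbind, lapply(seq_len(nrow(cr)), function(i) {
    use <- if (cr$catheter[i]) assessments[scorable] else assessments
    v <- vapply(use, function(a) a$points[[cr$id[i]]], numeric(1))
    v <- v[!is.na(v)]
    data.frame(id = cr$id[i], median = .q6(v, 0.5), n = length(v))
  }))
  structure(list(median = .q6(totals, 0.5), q25 = .q6(totals, 0.25),
                 q75 = .q6(totals, 0.75), per_criterion = per,
                 n_scored = sum(scorable), n_excluded = sum(!scorable)),
            class = "GssSummary")
}

#' @export
print.GssSummary <- function(x, ...) {
  cat(sprintf("GSS %s (%s-%s), n scored %d, n excluded %d\n",
              format(x$median), format(x$q25), format(x$q75), x$n_scored,
              x$n_excluded))
  invisible(x)
}
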