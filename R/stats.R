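# Stats module: paired and grouped comparison of original-vs-segmented
# measurements, mirroring the reporting of a clinical QCA validation study.

#' Normality check
#'
#' Shapiro-Wilk at alpha = 0.05. A constant vector is reported as a
#' degenerate, non-normal sample rather than crashing.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level for the verdict.
#' @return list: \code{normal} (logical verdict), \code{p_value},
#'   \code{statistic}, \code{degenerate}.
#' @export
checkNormality <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    .stopf("insufficient-data: normality testing needs n >= 3")
  if (stats::sd(values) == 0)
    return(list(normal = FALSE, p_value = NA_real_, statistic = NA_real_,
                degenerate = TRUE))
  s <- stats::shapiro.test(values)
  list(normal = unname(s$p.value > alpha), p_value = unname(s$p.value),
       statistic = unname(s$statistic), degenerate = FALSE)
}

#' Paired comparison of original vs segmented measurements
#'
#' Paired-samples t-test when the paired differences pass the normality
#' check, Wilcoxon signed-rank otherwise. Significance at p < 0.05. The
#' difference summary is the median (IQR) of the absolute per-case
#' differences, matching the reporting convention in which IQRs start at or
#' near 0.
#'
#' @param original,segmented paired numeric vectors (one value per case;
#'   excluded cases must already be removed).
#' @param parameter label for reporting (e.g. "Diameter at lesion (mm)").
#' @param units unit label.
#' @return list of class \code{ComparisonResult}: test name, p value, per-
#'   arm mean/sd and median (IQR), the absolute-difference median (IQR),
#'   n, and the significance verdict. All-zero differences are reported
#'   with p = 1 and a degeneracy flag.
#' @export
pairedCompare <- function(original, segmented, parameter = "", units = "") {
  keep <- !(is.na(original) | is.na(segmented))
  original <- original[keep]; segmented <- segmented[keep]
  n <- length(original)
  if (n < 3L || length(segmented) != n)
    .stopf("insufficient-data: paired comparison needs >= 3 complete pairs")
  d <- original - segmented
  arm <- function(x) list(mean = mean(x), sd = stats::sd(x),
                          median = .q6(x, 0.5), q25 = .q6(x, 0.25),
                          q75 = .q6(x, 0.75))
  absd <- abs(d)
  diff_summary <- list(median = .q6(absd, 0.5), q25 = .q6(absd, 0.25),
                       q75 = .q6(absd, 0.75))
  if (all(d == 0)) {
    res <- list(parameter = parameter, units = units,
                test = "degenerate (all differences zero)", p_value = 1,
                n = n, original = arm(original), segmented = arm(segmented),
                difference = diff_summary, significant = FALSE,
                degenerate = TRUE)
    return(structure(res, class = "ComparisonResult"))
  }
  norm <- checkNormality(d)
  if (isTRUE(norm$normal)) {
    ht <- stats::t.test(original, segmented, paired = TRUE)
    test <- "paired t-test"
  } else {
    ht <- stats::wilcox.test(original, segmented, paired = TRUE,
                             exact = FALSE)
    test <- "Wilcoxon signed-rank"
  }
  structure(list(parameter = parameter, units = units, test = test,
                 p_value = unname(ht$p.value), n = n,
                 original = arm(original), segmented = arm(segmented),
                 difference = diff_summary,
                 significant = unname(ht$p.value) < 0.05,
                 degenerate = FALSE),
            class = "ComparisonResult")
}

#' Grouped comparison of a measurement across independent groups
#'
#' Mann-Whitney (Wilcoxon rank-sum) for two groups, Kruskal-Wallis for more
#' than two; significance at p < 0.05.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length as \code{values}.
#' @param parameter label for reporting.
#' @return list of class \code{ComparisonResult} with per-group medians
#'   (IQR) and the test p value.
#' @export
groupCompare <- function(values, groups, parameter = "") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  tab <- table(groups)
  if (length(tab) < 2L)
    .stopf("insufficient-data: grouped comparison needs >= 2 groups")
  if (any(tab < 2L))
    .stopf("insufficient-data: every group needs n >= 2")
  if (length(tab) == 2L) {
    g <- names(tab)
    ht <- stats::wilcox.test(values[groups == g[1]], values[groups == g[2]],
                             exact = FALSE)
    test <- "Mann-Whitney"
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
    test <- "Kruskal-Wallis"
  }
  per_group <- do.call(rbind, lapply(names(tab), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), median = .q6(v, 0.5),
               q25 = .q6(v, 0.25), q75 = .q6(v, 0.75))
  }))
  structure(list(parameter = parameter, test = test,
                 p_value = unname(ht$p.value), groups = per_group,
                 significant = unname(ht$p.value) < 0.05),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s [%s]: p = %.4g%s\n",
              if (nzchar(x$parameter)) x$parameter else "comparison",
              x$test, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Median and interquartile range
#'
#' Type-6 quantiles (SPSS-style linear interpolation of order statistics),
#' the convention used throughout the package.
#'
#' @param values numeric vector, n >= 1.
#' @return named numeric: \code{median}, \code{q25}, \code{q75}.
#' @examples
#' medianIqr(c(0, 0.10, 0.17))
#' @export
medianIqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    .stopf("empty-input: medianIqr needs at least one value")
  c(median = .q6(values, 0.5), q25 = .q6(values, 0.25),
    q75 = .q6(values, 0.75))
}

#' Count with relative percentage, clinical-table style
#'
#' Formats "N (\%)" table cells: the percentage of \code{n} out of
#' \code{total}, rounded to the requested number of digits.
#'
#' @param n count.
#' @param total denominator, > 0.
#' @param digits decimal digits for the percentage (clinical tables
#'   typically print 0 or 1).
#' @return list: \code{n}, \code{percent}, and \code{label} ("n (p)").
#' @examples
#' countPercent(58, 123)$percent  # 47
#' @export
countPercent <- function(n, total, digits = 0) {
  if (total <= 0) .stopf("total must be > 0")
  p <- round(n / total * 100, digits)
  list(n = n, percent = p,
       label = sprintf("%d (%s)", n, format(p, trim = TRUE)))
}
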