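#' @include AllClasses.R
NULL

#' Normality gate (Shapiro-Wilk)
#'
#' Group comparisons are run only after checking that the data are
#' compatible with a normal distribution; Shapiro-Wilk at alpha = 0.05 is
#' used, appropriate for the small group sizes typical of these designs
#' (n = 4 mice).  Constant data are reported as not assessable.
#'
#' @param values numeric vector (n >= 3).
#' @param alpha significance level of the gate (default 0.05).
#' @return list with \code{passed} (logical, NA when not assessable) and
#'   \code{p}.
#' @examples
#' normalityCheck(rnorm(20))
#' @export
normalityCheck <- function(values, alpha = 0.05) {
  if (length(values) < 3L) stop("at least 3 values required")
  if (stats::var(values) == 0)
    return(list(passed = NA, p = NA_real_))
  sw <- stats::shapiro.test(values)
  list(passed = sw$p.value >= alpha, p = sw$p.value)
}

#' Significance stars from a p-value
#'
#' "***" for p <= 0.001, "**" for p <= 0.01, "*" for p <= 0.05 (boundaries
#' inclusive), "ns" otherwise.
#'
#' @param p p-value in [0, 1].
#' @return one of "ns", "*", "**", "***".
#' @examples
#' significanceStars(0.0008)  # "***"
#' @export
significanceStars <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else "ns"
}

#' Two-tailed two-sample t-test with normality gate
#'
#' Runs the Shapiro-Wilk gate on each group (warning on failure, still
#' computing the test), then a two-sided t-test with a 95% confidence
#' interval on the difference of means.  Welch's unequal-variance form is
#' the default, robust at small n; a pooled-variance mode is available.
#'
#' @param groupA,groupB numeric vectors (each n >= 2).
#' @param pooled logical; use the pooled-variance (equal variances) test
#'   (default FALSE = Welch).
#' @return A \linkS4class{TestResult}.
#' @examples
#' twoTailedT(c(1, 2, 3), c(11, 12, 13))
#' @export
twoTailedT <- function(groupA, groupB, pooled = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  gate <- function(v) {
    if (length(v) >= 3L) normalityCheck(v) else list(passed = NA, p = NA_real_)
  }
  nA <- gate(groupA); nB <- gate(groupB)
  if (isFALSE(nA$passed) || isFALSE(nB$passed))
    warning("a group failed the normality gate; t-test computed anyway")
  tt <- stats::t.test(groupA, groupB, alternative = "two.sided",
                      var.equal = pooled, conf.level = 0.95)
  new("TestResult", statistic = unname(tt$statistic), p = tt$p.value,
      ci95 = as.numeric(tt$conf.int),
      normalityP = c(nA$p, nB$p),
      normalityPassed = c(isTRUE(nA$passed), isTRUE(nB$passed)),
      stars = significanceStars(tt$p.value))
}

#' Write a machine- and human-readable statistics report
#'
#' Serializes group summaries and pairwise test results to JSON
#' (machine-readable) and CSV (human-readable): means +/- SEM, CVs,
#' optional fold changes, and t / p / stars per comparison.  More than 5
#' comparisons triggers a multiplicity flag in the report (no correction is
#' applied).
#'
#' @param summaries list of \linkS4class{GroupSummary}.
#' @param tests named list of \linkS4class{TestResult}; names are
#'   "groupA:groupB" pairs whose group names must appear in
#'   \code{summaries}.
#' @param outPath output path without extension; \code{<outPath>.json} and
#'   \code{<outPath>.csv} are written.
#' @param foldChanges optional named numeric vector of fold changes.
#' @return invisibly, the report list structure that was serialized.
#' @export
writeReport <- function(summaries, tests = list(), outPath,
                        foldChanges = NULL) {
  groupNames <- vapply(summaries, function(s) s@groupName, character(1))
  for (nm in names(tests)) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% groupNames))
      stop(sprintf("comparison '%s' names groups absent from the summaries", nm))
  }
  sumDf <- data.frame(
    group = groupNames,
    n = vapply(summaries, function(s) s@n, integer(1)),
    mean = vapply(summaries, function(s) s@mean, numeric(1)),
    sem = vapply(summaries, function(s) s@sem, numeric(1)),
    cvPercent = vapply(summaries, function(s) s@cvPercent, numeric(1))
  )
  testDf <- if (length(tests)) data.frame(
    comparison = names(tests),
    t = vapply(tests, function(x) x@statistic, numeric(1)),
    p = vapply(tests, function(x) x@p, numeric(1)),
    ciLow = vapply(tests, function(x) x@ci95[1], numeric(1)),
    ciHigh = vapply(tests, function(x) x@ci95[2], numeric(1)),
    stars = vapply(tests, function(x) x@stars, character(1))
  ) else data.frame()
  report <- list(summaries = sumDf, tests = testDf)
  if (!is.null(foldChanges))
    report$foldChanges <- as.list(foldChanges)
  if (length(tests) > 5L)
    report$multiplicityFlag <-
      sprintf("%d comparisons run without multiple-testing correction",
              length(tests))
  jsonlite::write_json(report, paste0(outPath, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(sumDf, paste0(outPath, "_summaries.csv"),
                   row.names = FALSE)
  if (nrow(testDf))
    utils::write.csv(testDf, paste0(outPath, "_tests.csv"),
                     row.names = FALSE)
  invisible(report)
}

#' Read back a report written by writeReport
#'
#' @param outPath the path stem passed to \code{\link{writeReport}}.
#' @return the report list (summaries and tests as data.frames).
#' @export
readReport <- function(outPath) {
  rep <- jsonlite::read_json(paste0(outPath, ".json"), simplifyVector = TRUE)
  rep
}
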