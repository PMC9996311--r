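## Condition-level statistics: per-condition medians, fold changes of the
## median effective diffusion coefficient, replicate-paired t-tests, and
## particle-intensity distributions.

#' Summarize one condition and replicate
#'
#' Takes the per-trajectory fit table produced by
#' \code{\link{analyzeTrajectories}} and computes the condition-level
#' medians of D_eff and alpha over all trajectories with a finite fit (the
#' standard "median D_eff per condition" summary). Per-trajectory average
#' mean intensities, when supplied, are carried through for
#' intensity-distribution analysis.
#'
#' @param records data.frame with at least \code{trajectory_id} and
#'   \code{D_eff_um2_per_s} (and optionally \code{alpha}) columns.
#' @param condition condition label.
#' @param replicate replicate label.
#' @param intensities optional numeric vector of per-trajectory average mean
#'   intensities.
#' @return a \code{\linkS4class{ConditionSummary}}.
#' @examples
#' rec <- data.frame(trajectory_id = c("a", "b", "c"),
#'                   D_eff_um2_per_s = c(1, 2, 3), alpha = c(.8, .9, 1))
#' summarizeCondition(rec, "control", "rep1")
#' @export
summarizeCondition <- function(records, condition, replicate = "rep1",
                               intensities = numeric(0)) {
  if (is.null(records) || nrow(records) == 0)
    stop("cannot summarize an empty record set")
  if (!"D_eff_um2_per_s" %in% names(records))
    stop("records must have a D_eff_um2_per_s column")
  a <- if ("alpha" %in% names(records)) records$alpha else NA_real_
  new("ConditionSummary",
      condition = as.character(condition),
      replicate = as.character(replicate),
      nTrajectories = nrow(records),
      medianDeff = stats::median(records$D_eff_um2_per_s, na.rm = TRUE),
      medianAlpha = if (all(is.na(a))) NA_real_ else
        stats::median(a, na.rm = TRUE),
      intensities = as.numeric(intensities),
      records = records)
}

#' @describeIn foldChange ratio of median D_eff, test over reference.
#' @export
setMethod("foldChange", signature("ConditionSummary", "ConditionSummary"),
  function(test, reference) {
    if (!is.finite(reference@medianDeff) || reference@medianDeff <= 0)
      stop("reference median D_eff must be positive")
    test@medianDeff / reference@medianDeff
  })

#' @describeIn foldChange ratio of two bare medians.
#' @export
setMethod("foldChange", signature("numeric", "numeric"),
  function(test, reference) {
    if (reference <= 0) stop("reference median must be positive")
    test / reference
  })

#' Replicate-paired two-tailed t-test
#'
#' Classical paired t-test on per-replicate scalars (typically the
#' per-replicate median D_eff or median alpha of two conditions, paired by
#' biological replicate). With the usual three biological replicates this is
#' a 2-df test; that small-n limitation is inherent to the design and is
#' reported as-is. When every paired difference is exactly zero the t
#' statistic is undefined and the result is flagged degenerate instead of
#' being assigned a p-value.
#'
#' @param valuesA,valuesB equal-length numeric vectors (length >= 2), paired
#'   by position.
#' @return a \code{\linkS4class{ComparisonResult}} whose \code{foldChanges}
#'   slot holds the per-replicate ratios \code{valuesA / valuesB}, with
#'   their mean and SD, the paired t-test on the raw values, and a
#'   one-sample t-test of the ratios against 1.
#' @examples
#' pairedTTest(c(1.2, 1.4, 1.1), c(1.0, 1.1, 0.9))
#' @export
pairedTTest <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB))
    stop("paired vectors must have equal length")
  if (length(valuesA) < 2)
    stop("need at least 2 replicate pairs")
  fc <- valuesA / valuesB
  diffs <- valuesA - valuesB
  degenerate <- stats::sd(diffs) == 0
  if (degenerate) {
    return(new("ComparisonResult", foldChanges = fc,
               meanFold = mean(fc), sdFold = stats::sd(fc),
               tStatistic = NA_real_, pValue = NA_real_,
               tStatisticFold = NA_real_, pValueFold = NA_real_,
               test = "paired two-tailed t", degenerate = TRUE))
  }
  tt <- stats::t.test(valuesA, valuesB, paired = TRUE,
                      alternative = "two.sided")
  ttf <- if (stats::sd(fc) > 0)
    stats::t.test(fc, mu = 1, alternative = "two.sided") else NULL
  new("ComparisonResult", foldChanges = fc,
      meanFold = mean(fc), sdFold = stats::sd(fc),
      tStatistic = unname(tt$statistic), pValue = tt$p.value,
      tStatisticFold = if (is.null(ttf)) NA_real_ else unname(ttf$statistic),
      pValueFold = if (is.null(ttf)) NA_real_ else ttf$p.value,
      test = "paired two-tailed t", degenerate = FALSE)
}

#' Compare two conditions across replicates
#'
#' Computes the per-replicate fold change of median D_eff (test over
#' reference, replicates paired by label) and the paired t-test on the raw
#' per-replicate medians; the per-replicate construction mirrors the
#' "fold change of median D_eff from n biological replicates (mean +/- SD)"
#' summary rather than pooling trajectories across replicates.
#'
#' @param testSummaries,referenceSummaries lists of
#'   \code{\linkS4class{ConditionSummary}} objects; replicate labels must
#'   match one-to-one.
#' @param statistic which per-replicate scalar to compare:
#'   \code{"medianDeff"} (default) or \code{"medianAlpha"}.
#' @return a \code{\linkS4class{ComparisonResult}}.
#' @export
compareConditions <- function(testSummaries, referenceSummaries,
                              statistic = c("medianDeff", "medianAlpha")) {
  statistic <- match.arg(statistic)
  repT <- vapply(testSummaries, function(s) s@replicate, character(1))
  repR <- vapply(referenceSummaries, function(s) s@replicate, character(1))
  if (!setequal(repT, repR) || anyDuplicated(repT) || anyDuplicated(repR))
    stop("replicate labels must match one-to-one between conditions")
  ord <- match(sort(repT), repT)
  ordR <- match(sort(repT), repR)
  getStat <- function(s) slot(s, statistic)
  a <- vapply(testSummaries[ord], getStat, numeric(1))
  b <- vapply(referenceSummaries[ordR], getStat, numeric(1))
  pairedTTest(a, b)
}

#' Particle-intensity distribution summary
#'
#' Normalized histogram (probability masses summing to 1), median and
#' interquartile range of per-trajectory average mean intensities, used to
#' compare particle brightness -- a proxy for particle size -- between
#' conditions.
#'
#' @param x numeric vector of intensities, or a
#'   \code{\linkS4class{ConditionSummary}} (its \code{intensities} slot).
#' @param bins number of equal-width bins (default 30).
#' @return list with \code{breaks}, \code{mids}, \code{prob} (bin
#'   probabilities summing to 1), \code{median} and \code{iqr}.
#' @export
intensityDistribution <- function(x, bins = 30) {
  if (is(x, "ConditionSummary")) x <- x@intensities
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty intensity vector")
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  list(breaks = h$breaks, mids = h$mids, prob = h$counts / length(x),
       median = stats::median(x), iqr = stats::IQR(x))
}

#' Rank-sum comparison of two intensity distributions
#'
#' Two-sample Wilcoxon rank-sum test between the per-trajectory average
#' intensities of two conditions.
#'
#' @param a,b numeric vectors or \code{\linkS4class{ConditionSummary}}
#'   objects.
#' @return list with \code{statistic} (W) and \code{p_value}.
#' @export
compareIntensities <- function(a, b) {
  if (is(a, "ConditionSummary")) a <- a@intensities
  if (is(b, "ConditionSummary")) b <- b@intensities
  if (!length(a) || !length(b)) stop("empty intensity vector")
  w <- stats::wilcox.test(a, b, exact = FALSE)
  list(statistic = unname(w$statistic), p_value = w$p.value)
}
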