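#' @include AllClasses.R
NULL

#' Per-quintile summary metrics
#'
#' Computes the chosen summary metric independently on each contiguous
#' segment (quintile) of a time series, using only that segment's
#' un-censored frames. Every segment must pass the per-segment sufficiency
#' rule (at least `minPerSegment` un-censored frames, default 100);
#' otherwise the subject is flagged by an error of class
#' `"insufficientSegmentData"` and should be excluded from the panel.
#'
#' @param series A [ParcelTimeSeries-class] with segment labels.
#' @param spec A [SubNetworkSpec-class] (for `average_connectivity`) or
#'   `NULL` for the whole matrix.
#' @param metric `"average_connectivity"` (default), `"global_clustering"`
#'   or `"path_length"`.
#' @param retain Edge-retention fraction for the graph metrics (default
#'   0.70).
#' @param minPerSegment Per-segment sufficiency threshold (default 100).
#' @param clip Passed to [connectivityMatrix()].
#' @return Numeric vector with one metric value per segment.
#' @export
quintileMetrics <- function(series, spec = NULL,
                            metric = c("average_connectivity",
                                       "global_clustering", "path_length"),
                            retain = 0.70, minPerSegment = 100,
                            clip = FALSE) {
  stopifnot(is(series, "ParcelTimeSeries"))
  metric <- match.arg(metric)
  labs <- segmentLabels(series)
  segs <- unique(labs)
  cen <- censored(series)
  counts <- vapply(segs, function(s) sum(!cen[labs == s]), integer(1))
  if (any(counts < minPerSegment)) {
    bad <- segs[counts < minPerSegment]
    stop(structure(class = c("insufficientSegmentData", "error", "condition"),
                   list(message = sprintf(
                     "segment(s) %s have fewer than %d un-censored frames (%s); subject excluded",
                     paste(bad, collapse = ", "), minPerSegment,
                     paste(counts[counts < minPerSegment], collapse = ", ")),
                     call = sys.call())))
  }
  vapply(segs, function(s) {
    idx <- which(labs == s)
    sub <- ParcelTimeSeries(as.matrix(series)[idx, , drop = FALSE],
                            tr = tr(series), regionIds = regionIds(series),
                            censorMask = CensorMask(cen[idx],
                                                    censorReason(censorMask(series))[idx]))
    cmIds <- if (is(spec, "SubNetworkSpec"))
      union(spec@nodesA, spec@nodesB) else NULL
    cm <- connectivityMatrix(sub, nodeSet = cmIds, clip = clip)
    switch(metric,
           average_connectivity = averageConnectivity(cm, spec),
           global_clustering =
             globalClustering(proportionalThreshold(cm, retain)),
           path_length = as.numeric(
             characteristicPathLength(proportionalThreshold(cm, retain))))
  }, numeric(1))
}

#' Assemble a metric panel across subjects
#'
#' Applies [quintileMetrics()] to each subject's series and stacks the
#' results into a [MetricPanel-class], silently excluding subjects that fail
#' the per-segment sufficiency rule (their ids are reported in the
#' `excluded` attribute).
#'
#' @param seriesList Named list of [ParcelTimeSeries-class] objects.
#' @param spec,metric,retain,minPerSegment,clip See [quintileMetrics()].
#' @param sample Sample label for the panel.
#' @return A [MetricPanel-class] with attribute `excluded`.
#' @export
quintilePanel <- function(seriesList, spec = NULL,
                          metric = "average_connectivity", retain = 0.70,
                          minPerSegment = 100, clip = FALSE,
                          sample = "sample") {
  rows <- list()
  excluded <- character(0)
  ids <- names(seriesList)
  if (is.null(ids)) ids <- paste0("S", seq_along(seriesList))
  for (i in seq_along(seriesList)) {
    v <- tryCatch(
      quintileMetrics(seriesList[[i]], spec, metric, retain, minPerSegment,
                      clip),
      insufficientSegmentData = function(e) NULL)
    if (is.null(v)) excluded <- c(excluded, ids[i]) else rows[[ids[i]]] <- v
  }
  if (length(rows) < 3L)
    stop("fewer than 3 subjects with sufficient data in every segment")
  panel <- MetricPanel(do.call(rbind, rows), metric = metric, sample = sample)
  attr(panel, "excluded") <- excluded
  panel
}

#' Cronbach's alpha with Feldt confidence interval
#'
#' Internal consistency over k parallel measurements (here, the five
#' quintile estimates): `alpha = k/(k-1) * (1 - sum(var_i) / var_total)`,
#' where `var_i` is the across-subject variance of condition i and
#' `var_total` the across-subject variance of the condition sum. The 95%
#' confidence interval uses the Feldt F-distribution method with
#' `n - 1` and `(n - 1)(k - 1)` degrees of freedom. Values above 0.7 are
#' conventionally considered adequate.
#'
#' @param panel A [MetricPanel-class] (or bare matrix), subjects in rows,
#'   conditions in columns.
#' @param ciLevel Confidence level (default 0.95).
#' @return A [ReliabilityResult-class].
#' @examples
#' p <- MetricPanel(matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 7, 4, 7, 9),
#'                         nrow = 4, byrow = TRUE))
#' cronbachAlpha(p)
#' @export
cronbachAlpha <- function(panel, ciLevel = 0.95) {
  v <- if (is(panel, "MetricPanel")) panelValues(panel) else as.matrix(panel)
  n <- nrow(v)
  k <- ncol(v)
  stopifnot(n >= 3L, k >= 2L)
  varTotal <- stats::var(rowSums(v))
  if (varTotal <= 0)
    stop("zero total variance across subjects; alpha undefined")
  a <- k / (k - 1) * (1 - sum(apply(v, 2, stats::var)) / varTotal)
  p <- (1 - ciLevel) / 2
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  lo <- 1 - (1 - a) * stats::qf(1 - p, df1, df2)
  hi <- 1 - (1 - a) * stats::qf(p, df1, df2)
  new("ReliabilityResult", estimate = a, ciLow = lo, ciHigh = hi,
      kind = "cronbach_alpha", nSubjects = as.integer(n),
      nConditions = as.integer(k), degenerate = FALSE)
}

.anovaMeanSquares <- function(v) {
  n <- nrow(v)
  k <- ncol(v)
  gm <- mean(v)
  rm <- rowMeans(v)
  cm <- colMeans(v)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((v - gm)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Agreement intraclass correlation (two-way random, single measures)
#'
#' Test-retest reliability of single measurements across sessions: the
#' absolute-agreement ICC from a two-way random-effects subjects x sessions
#' ANOVA, `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' (ICC(A,1) in the McGraw-Wong taxonomy, ICC(2,1) in Shrout-Fleiss).
#' Unlike the consistency form (`type = "consistency"`), it penalizes
#' systematic session offsets. The 95% interval is the standard F-based
#' interval with Satterthwaite degrees of freedom. Values above 0.6 are
#' conventionally considered moderate, above 0.8 substantial.
#'
#' @param panel A [MetricPanel-class] (or bare matrix), subjects in rows,
#'   sessions in columns.
#' @param ciLevel Confidence level (default 0.95).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return A [ReliabilityResult-class]. A degenerate ANOVA (zero error mean
#'   square, i.e. sessions identical up to subject effects) yields ICC = 1
#'   with the `degenerate` flag set.
#' @export
iccAgreement <- function(panel, ciLevel = 0.95,
                         type = c("agreement", "consistency")) {
  type <- match.arg(type)
  v <- if (is(panel, "MetricPanel")) panelValues(panel) else as.matrix(panel)
  stopifnot(nrow(v) >= 3L, ncol(v) >= 2L)
  ms <- .anovaMeanSquares(v)
  n <- ms$n
  k <- ms$k
  kind <- paste0("icc_", type)
  if (ms$mse <= .Machine$double.eps * mean(v^2)) {
    return(new("ReliabilityResult", estimate = 1, ciLow = NA_real_,
               ciHigh = NA_real_, kind = kind, nSubjects = as.integer(n),
               nConditions = as.integer(k), degenerate = TRUE))
  }
  p <- 1 - (1 - ciLevel) / 2
  if (type == "consistency") {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    f <- ms$msr / ms$mse
    fl <- f / stats::qf(p, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(p, (n - 1) * (k - 1), n - 1)
    return(new("ReliabilityResult", estimate = icc,
               ciLow = (fl - 1) / (fl + k - 1), ciHigh = (fu - 1) / (fu + k - 1),
               kind = kind, nSubjects = as.integer(n),
               nConditions = as.integer(k), degenerate = FALSE))
  }
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  # Satterthwaite df for the absolute-agreement interval (McGraw & Wong)
  fj <- ms$msc / ms$mse
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  vnum <- (a * fj + b)^2
  vden <- a^2 * fj^2 / (k - 1) + b^2 / (n - 1)
  df2 <- vnum / vden
  fl <- stats::qf(p, n - 1, df2)
  fu <- stats::qf(p, df2, n - 1)
  lo <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  new("ReliabilityResult", estimate = icc, ciLow = lo, ciHigh = hi,
      kind = kind, nSubjects = as.integer(n), nConditions = as.integer(k),
      degenerate = FALSE)
}

#' Replication check across samples
#'
#' A metric replicates across samples when (i) a one-way ANOVA finds no
#' significant difference of sample means (p >= `level`) and (ii) the
#' reliability point estimate of every non-reference sample falls inside
#' the reference sample's 95% confidence interval.
#'
#' @param metricValues Named list of numeric vectors, one per sample
#'   (subject-level metric values); the first element is the reference
#'   sample.
#' @param reliabilityResults Optional named list of
#'   [ReliabilityResult-class] objects, one per sample, in the same order.
#' @param level Significance level for the mean comparison (default 0.05).
#' @return List with `meansReplicated` (logical), `anovaP`, and — when
#'   reliability results are supplied — `reliabilityReplicated` (named
#'   logical per non-reference sample) and `referenceCI`.
#' @export
replicationCheck <- function(metricValues, reliabilityResults = NULL,
                             level = 0.05) {
  stopifnot(is.list(metricValues), length(metricValues) >= 2L)
  ids <- names(metricValues)
  if (is.null(ids)) ids <- paste0("sample", seq_along(metricValues))
  y <- unlist(metricValues, use.names = FALSE)
  grp <- factor(rep(ids, lengths(metricValues)), levels = ids)
  pval <- stats::anova(stats::lm(y ~ grp))[["Pr(>F)"]][1]
  out <- list(meansReplicated = pval >= level, anovaP = pval)
  if (!is.null(reliabilityResults)) {
    stopifnot(length(reliabilityResults) == length(metricValues))
    ref <- reliabilityResults[[1]]
    stopifnot(is(ref, "ReliabilityResult"))
    others <- reliabilityResults[-1]
    inCI <- vapply(others, function(r)
      r@estimate >= ref@ciLow && r@estimate <= ref@ciHigh, logical(1))
    names(inCI) <- ids[-1]
    out$reliabilityReplicated <- inCI
    out$referenceCI <- c(ref@ciLow, ref@ciHigh)
  }
  out
}
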