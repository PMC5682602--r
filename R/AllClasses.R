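#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- CensorMask

#' Frame censoring mask
#'
#' Per-frame censoring flags together with the provenance of each censored
#' frame: `"motion"` (framewise displacement above threshold), `"intensity"`
#' (scaled signal-intensity difference above threshold), or `"expansion"`
#' (temporal-mask expansion around a spike). Un-censored frames carry an
#' empty provenance string.
#'
#' @slot censored Logical vector, `TRUE` for censored frames.
#' @slot reason Character vector of the same length; one of `"motion"`,
#'   `"intensity"`, `"expansion"` or `""`.
#' @export
setClass("CensorMask",
  representation(censored = "logical", reason = "character"))

setValidity("CensorMask", function(object) {
  if (length(object@censored) != length(object@reason))
    return("'censored' and 'reason' must have equal length")
  if (anyNA(object@censored))
    return("'censored' must not contain NA")
  bad <- !object@reason %in% c("", "motion", "intensity", "expansion")
  if (any(bad))
    return("unknown provenance label in 'reason'")
  if (any(object@censored & object@reason == ""))
    return("censored frames must carry a provenance label")
  if (any(!object@censored & object@reason != ""))
    return("un-censored frames must have empty provenance")
  TRUE
})

#' Construct a censoring mask
#'
#' @param censored Logical vector of per-frame censoring flags.
#' @param reason Character vector of provenance labels (`"motion"`,
#'   `"intensity"`, `"expansion"`); defaults to `"motion"` for every
#'   censored frame.
#' @return A [CensorMask-class] object.
#' @examples
#' CensorMask(c(FALSE, TRUE, FALSE), c("", "motion", ""))
#' @export
CensorMask <- function(censored, reason = NULL) {
  censored <- as.logical(censored)
  if (is.null(reason)) {
    reason <- ifelse(censored, "motion", "")
  }
  new("CensorMask", censored = censored, reason = reason)
}

#' @rdname accessors
#' @export
setMethod("censored", "CensorMask", function(x) x@censored)

#' @rdname accessors
#' @export
setMethod("censorReason", "CensorMask", function(x) x@reason)

#' @export
setMethod("length", "CensorMask", function(x) length(x@censored))

setMethod("show", "CensorMask", function(object) {
  n <- length(object@censored)
  k <- sum(object@censored)
  cat(sprintf("CensorMask: %d frames, %d censored (%.1f%%)\n",
              n, k, if (n > 0) 100 * k / n else 0))
  if (k > 0) {
    tab <- table(object@reason[object@censored])
    cat("  provenance:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

## --------------------------------------------------------- ParcelTimeSeries

#' Parcel-averaged BOLD time series
#'
#' A time-by-region matrix of parcel-averaged BOLD signal with its
#' repetition time, censoring mask and contiguous segment labels (the five
#' task blocks used for the quintile internal-consistency analysis).
#'
#' @slot values Numeric matrix, rows = time points, columns = regions.
#' @slot tr Repetition time in seconds.
#' @slot regionIds Character vector of region identifiers (column names).
#' @slot censorMask A [CensorMask-class] of length `nrow(values)`.
#' @slot segmentLabels Integer vector of contiguous, non-decreasing block
#'   labels partitioning the frames.
#' @export
setClass("ParcelTimeSeries",
  representation(values = "matrix", tr = "numeric", regionIds = "character",
                 censorMask = "CensorMask", segmentLabels = "integer"))

setValidity("ParcelTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be numeric")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("'tr' must be a single positive number (seconds)")
  if (length(object@regionIds) != ncol(v))
    return("'regionIds' length must equal the number of columns")
  if (anyDuplicated(object@regionIds))
    return("duplicate region ids")
  if (length(object@censorMask) != nrow(v))
    return("censor mask length must equal the number of frames")
  if (length(object@segmentLabels) != nrow(v))
    return("'segmentLabels' length must equal the number of frames")
  d <- diff(object@segmentLabels)
  if (length(d) && (any(d < 0) || any(d > 1)))
    return("'segmentLabels' must be contiguous and non-decreasing")
  keep <- !object@censorMask@censored
  if (any(!is.finite(v[keep, , drop = FALSE])))
    return("non-finite values in un-censored frames")
  TRUE
})

#' Construct a parcel time series
#'
#' @param values Numeric matrix, rows = time points, columns = regions.
#' @param tr Repetition time in seconds.
#' @param regionIds Region identifiers; defaults to the column names of
#'   `values` (or `"R1"`, `"R2"`, ... when absent).
#' @param censorMask A [CensorMask-class]; defaults to all frames retained.
#' @param segmentLabels Integer block labels; defaults to a single block.
#'   Use [makeSegmentLabels()] for equal contiguous quintiles.
#' @return A [ParcelTimeSeries-class] object.
#' @examples
#' x <- ParcelTimeSeries(matrix(rnorm(40), 10, 4), tr = 2.5)
#' nFrames(x); nRegions(x)
#' @export
ParcelTimeSeries <- function(values, tr, regionIds = NULL,
                             censorMask = NULL, segmentLabels = NULL) {
  values <- as.matrix(values)
  if (is.null(regionIds)) {
    regionIds <- colnames(values)
    if (is.null(regionIds)) regionIds <- paste0("R", seq_len(ncol(values)))
  }
  regionIds <- as.character(regionIds)
  colnames(values) <- regionIds
  if (is.null(censorMask))
    censorMask <- CensorMask(rep(FALSE, nrow(values)))
  if (is.null(segmentLabels))
    segmentLabels <- rep(1L, nrow(values))
  new("ParcelTimeSeries", values = values, tr = as.numeric(tr),
      regionIds = regionIds, censorMask = censorMask,
      segmentLabels = as.integer(segmentLabels))
}

#' Contiguous equal segment labels
#'
#' Labels `nFrames` time points as `nSegments` contiguous blocks of (near-)
#' equal length, e.g. the five 120-frame task blocks of a 600-frame session.
#'
#' @param nFrames Number of time points.
#' @param nSegments Number of contiguous blocks (default 5, quintiles).
#' @return Integer vector of length `nFrames`.
#' @examples
#' table(makeSegmentLabels(600))
#' @export
makeSegmentLabels <- function(nFrames, nSegments = 5L) {
  stopifnot(nFrames >= nSegments, nSegments >= 1L)
  as.integer(sort(rep_len(seq_len(nSegments), nFrames)))
}

#' @rdname accessors
#' @export
setMethod("tr", "ParcelTimeSeries", function(x) x@tr)

#' @rdname accessors
#' @export
setMethod("regionIds", "ParcelTimeSeries", function(x) x@regionIds)

#' @rdname accessors
#' @export
setMethod("nFrames", "ParcelTimeSeries", function(x) nrow(x@values))

#' @rdname accessors
#' @export
setMethod("nRegions", "ParcelTimeSeries", function(x) ncol(x@values))

#' @rdname accessors
#' @export
setMethod("censorMask", "ParcelTimeSeries", function(x) x@censorMask)

#' @rdname accessors
#' @export
setMethod("censored", "ParcelTimeSeries", function(x) x@censorMask@censored)

#' @rdname accessors
#' @export
setMethod("segmentLabels", "ParcelTimeSeries", function(x) x@segmentLabels)

#' @export
setMethod("as.matrix", "ParcelTimeSeries", function(x, ...) x@values)

setMethod("show", "ParcelTimeSeries", function(object) {
  cat(sprintf(
    "ParcelTimeSeries: %d frames x %d regions, TR = %g s, %d censored\n",
    nrow(object@values), ncol(object@values), object@tr,
    sum(object@censorMask@censored)))
  segs <- table(object@segmentLabels)
  cat(sprintf("  segments: %d (%s frames)\n", length(segs),
              paste(segs, collapse = ", ")))
})

## ------------------------------------------------------- ConnectivityMatrix

#' Fisher-Z magnitude connectivity matrix
#'
#' Symmetric region-by-region matrix of absolute Fisher-Z transformed
#' Pearson correlations with zero diagonal, plus the number of un-censored
#' frames the correlations were computed from.
#'
#' @slot values Symmetric numeric matrix, entries >= 0, zero diagonal.
#' @slot regionIds Character vector of region identifiers.
#' @slot nFramesUsed Number of frames entering every pairwise correlation.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", regionIds = "character",
                 nFramesUsed = "integer"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (length(object@regionIds) != nrow(v))
    return("'regionIds' length must equal matrix dimension")
  if (anyDuplicated(object@regionIds)) return("duplicate region ids")
  if (any(!is.finite(v))) return("non-finite entries")
  if (any(v < 0)) return("entries must be non-negative (Fisher-Z magnitudes)")
  if (any(abs(diag(v)) > 0)) return("diagonal must be zero")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-10)))
    return("matrix must be symmetric")
  TRUE
})

#' Construct a connectivity matrix object
#'
#' @param values Symmetric non-negative matrix of Fisher-Z magnitudes with
#'   zero diagonal.
#' @param regionIds Region identifiers; defaults to row names.
#' @param nFramesUsed Number of un-censored frames used (default `NA`-free 0
#'   when unknown).
#' @return A [ConnectivityMatrix-class] object.
#' @export
ConnectivityMatrix <- function(values, regionIds = NULL, nFramesUsed = 0L) {
  values <- as.matrix(values)
  if (is.null(regionIds)) {
    regionIds <- rownames(values)
    if (is.null(regionIds)) regionIds <- paste0("R", seq_len(nrow(values)))
  }
  regionIds <- as.character(regionIds)
  dimnames(values) <- list(regionIds, regionIds)
  new("ConnectivityMatrix", values = values, regionIds = regionIds,
      nFramesUsed = as.integer(nFramesUsed))
}

#' @rdname accessors
#' @export
setMethod("regionIds", "ConnectivityMatrix", function(x) x@regionIds)

#' @rdname accessors
#' @export
setMethod("nFramesUsed", "ConnectivityMatrix", function(x) x@nFramesUsed)

#' @export
setMethod("as.matrix", "ConnectivityMatrix", function(x, ...) x@values)

#' @export
setMethod("dim", "ConnectivityMatrix", function(x) dim(x@values))

setMethod("show", "ConnectivityMatrix", function(object) {
  ut <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "ConnectivityMatrix: %d x %d regions, %d frames used\n",
    nrow(object@values), ncol(object@values), object@nFramesUsed))
  if (length(ut))
    cat(sprintf("  |Fisher Z|: mean %.3f, range [%.3f, %.3f]\n",
                mean(ut), min(ut), max(ut)))
})

## ----------------------------------------------------------- SubNetworkSpec

#' Sub-network specification
#'
#' Defines a node set (within-set averages, `between = FALSE`) or a pair of
#' disjoint node sets (between-set averages, `between = TRUE`) over which
#' connectivity is summarized. The three canonical specifications for the
#' default mode network are produced by [deriveSubnetworks()]:
#' `whole_dmn`, `anterior` (medial-prefrontal midline regions) and
#' `posterior_to_anterior` (posterior-cingulate to anterior, between-set).
#'
#' @slot name Specification name.
#' @slot nodesA Character vector of region ids.
#' @slot nodesB Character vector; equal to `nodesA` for within-set specs,
#'   disjoint from it for between-set specs.
#' @slot between Logical; `TRUE` for between-set averages.
#' @export
setClass("SubNetworkSpec",
  representation(name = "character", nodesA = "character",
                 nodesB = "character", between = "logical"))

setValidity("SubNetworkSpec", function(object) {
  if (length(object@nodesA) == 0L || length(object@nodesB) == 0L)
    return("node sets must be non-empty")
  if (anyDuplicated(object@nodesA) || anyDuplicated(object@nodesB))
    return("duplicate region ids in a node set")
  if (object@between) {
    if (length(intersect(object@nodesA, object@nodesB)))
      return("between-set node sets must be disjoint")
  } else {
    if (!setequal(object@nodesA, object@nodesB))
      return("within-set specs must have nodesB equal to nodesA")
  }
  TRUE
})

#' Construct a sub-network specification
#'
#' @param name Specification name.
#' @param nodesA Region ids of the (first) node set.
#' @param nodesB Region ids of the second node set for between-set specs;
#'   defaults to `nodesA` (within-set).
#' @param between Logical; `TRUE` for a between-set specification.
#' @return A [SubNetworkSpec-class] object.
#' @examples
#' SubNetworkSpec("anterior", c("1", "2", "3"))
#' SubNetworkSpec("posterior_to_anterior", c("9"), c("1", "2"), between = TRUE)
#' @export
SubNetworkSpec <- function(name, nodesA, nodesB = nodesA, between = FALSE) {
  new("SubNetworkSpec", name = as.character(name),
      nodesA = as.character(nodesA), nodesB = as.character(nodesB),
      between = isTRUE(between))
}

setMethod("show", "SubNetworkSpec", function(object) {
  if (object@between) {
    cat(sprintf("SubNetworkSpec '%s': between-set, |A| = %d, |B| = %d\n",
                object@name, length(object@nodesA), length(object@nodesB)))
  } else {
    cat(sprintf("SubNetworkSpec '%s': within-set, %d regions\n",
                object@name, length(object@nodesA)))
  }
})

## ------------------------------------------------------------ WeightedGraph

#' Thresholded weighted undirected graph
#'
#' The graph form of a connectivity matrix after proportional thresholding:
#' strictly positive edge weights in Fisher-Z units, no self loops.
#'
#' @slot nodes Character vector of node (region) ids.
#' @slot edges Data frame with columns `from`, `to`, `weight` (one row per
#'   unordered pair, `from` < `to` lexicographically in node order).
#' @slot retention Fraction of possible edges the threshold aimed to keep.
#' @slot isolatedNodes Node ids left without any edge.
#' @slot connected Logical; whether the retained graph is connected.
#' @export
setClass("WeightedGraph",
  representation(nodes = "character", edges = "data.frame",
                 retention = "numeric", isolatedNodes = "character",
                 connected = "logical"))

setValidity("WeightedGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges must have columns from/to/weight")
  if (nrow(e)) {
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      return("edge weights must be finite and strictly positive")
    if (any(e$from == e$to)) return("self loops are not allowed")
    if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
      return("edge endpoints must be graph nodes")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) return("duplicate edges")
  }
  TRUE
})

#' Construct a weighted graph
#'
#' @param nodes Character vector of node ids.
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param retention Edge-retention fraction that produced the graph
#'   (default 1).
#' @return A [WeightedGraph-class] object.
#' @export
WeightedGraph <- function(nodes, edges, retention = 1) {
  nodes <- as.character(nodes)
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  iso <- names(deg)[deg == 0L]
  conn <- if (length(nodes) <= 1L) TRUE else {
    g <- .asIgraph(nodes, edges)
    igraph::is_connected(g)
  }
  new("WeightedGraph", nodes = nodes, edges = edges,
      retention = as.numeric(retention), isolatedNodes = iso,
      connected = conn)
}

.asIgraph <- function(nodes, edges, cost = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  if (!is.null(cost)) igraph::E(g)$cost <- cost
  g
}

#' @rdname accessors
#' @export
setMethod("edgeList", "WeightedGraph", function(x) x@edges)

setMethod("show", "WeightedGraph", function(object) {
  cat(sprintf(
    "WeightedGraph: %d nodes, %d edges (retention %.0f%%), %s\n",
    length(object@nodes), nrow(object@edges), 100 * object@retention,
    if (object@connected) "connected" else "disconnected"))
  if (length(object@isolatedNodes))
    cat("  isolated nodes:", paste(object@isolatedNodes, collapse = ", "),
        "\n")
})

## -------------------------------------------------------------- MetricPanel

#' Subjects-by-conditions metric panel
#'
#' A complete matrix of one summary metric across repeated conditions — the
#' five quintile estimates for internal consistency, or the two sessions for
#' test-retest reliability. Subjects failing the data-sufficiency rules are
#' excluded before panel construction, so no missing cells are allowed.
#'
#' @slot values Numeric matrix, rows = subjects, columns = conditions.
#' @slot metric Name of the summary metric.
#' @slot sample Sample label.
#' @export
setClass("MetricPanel",
  representation(values = "matrix", metric = "character",
                 sample = "character"))

setValidity("MetricPanel", function(object) {
  v <- object@values
  if (anyNA(v) || any(!is.finite(v))) return("panel must have no missing cells")
  if (ncol(v) < 2L) return("at least 2 conditions required")
  if (nrow(v) < 3L) return("at least 3 subjects required")
  TRUE
})

#' Construct a metric panel
#'
#' @param values Numeric matrix, subjects in rows, conditions in columns.
#' @param metric Metric name (default `"average_connectivity"`).
#' @param sample Sample label (default `"sample"`).
#' @return A [MetricPanel-class] object.
#' @export
MetricPanel <- function(values, metric = "average_connectivity",
                        sample = "sample") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("C", seq_len(ncol(values)))
  new("MetricPanel", values = values, metric = as.character(metric),
      sample = as.character(sample))
}

#' @rdname accessors
#' @export
setMethod("panelValues", "MetricPanel", function(x) x@values)

#' @export
setMethod("dim", "MetricPanel", function(x) dim(x@values))

setMethod("show", "MetricPanel", function(object) {
  cat(sprintf("MetricPanel '%s' (%s): %d subjects x %d conditions\n",
              object@metric, object@sample, nrow(object@values),
              ncol(object@values)))
})

## -------------------------------------------------------- ReliabilityResult

#' Reliability estimate with confidence interval
#'
#' @slot estimate Point estimate (Cronbach's alpha or ICC).
#' @slot ciLow,ciHigh 95% confidence bounds.
#' @slot kind `"cronbach_alpha"` or `"icc_agreement"` (or
#'   `"icc_consistency"`).
#' @slot nSubjects,nConditions Panel dimensions.
#' @slot degenerate Logical; `TRUE` when the ANOVA was degenerate (zero
#'   error mean square) and the interval is not meaningful.
#' @export
setClass("ReliabilityResult",
  representation(estimate = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 kind = "character", nSubjects = "integer",
                 nConditions = "integer", degenerate = "logical"))

setValidity("ReliabilityResult", function(object) {
  if (!object@degenerate &&
      (object@ciLow > object@estimate + 1e-8 ||
       object@ciHigh < object@estimate - 1e-8))
    return("confidence interval must bracket the estimate")
  TRUE
})

setMethod("show", "ReliabilityResult", function(object) {
  lab <- switch(object@kind,
                cronbach_alpha = "Cronbach's alpha",
                icc_agreement = "ICC (two-way random, absolute agreement)",
                icc_consistency = "ICC (two-way random, consistency)",
                object@kind)
  cat(sprintf("%s = %.2f [95%% CI %.2f, %.2f]  (n = %d, k = %d)%s\n",
              lab, object@estimate, object@ciLow, object@ciHigh,
              object@nSubjects, object@nConditions,
              if (object@degenerate) "  [degenerate]" else ""))
})

## ---------------------------------------------------------------- NormTable

#' Normative constants table
#'
#' Per-network, per-age-stratum normative mean, standard deviation,
#' 25th/75th percentile band and sample size for average Fisher-Z
#' connectivity. See [builtinNorms()] for the published constants.
#'
#' @slot entries Data frame with columns `network`, `stratum`, `mean`, `sd`,
#'   `p25`, `p75`, `n`.
#' @export
setClass("NormTable", representation(entries = "data.frame"))

setValidity("NormTable", function(object) {
  e <- object@entries
  need <- c("network", "stratum", "mean", "sd", "p25", "p75", "n")
  if (!all(need %in% names(e))) return("missing norm table columns")
  if (any(e$sd <= 0)) return("normative sd must be positive")
  if (any(e$p25 >= e$p75)) return("p25 must be below p75")
  if (anyDuplicated(e[, c("network", "stratum")]))
    return("duplicate network/stratum entry")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("normEntries", "NormTable", function(x) x@entries)

setMethod("show", "NormTable", function(object) {
  cat(sprintf("NormTable: %d entries\n", nrow(object@entries)))
  print(object@entries, row.names = FALSE)
})

## ------------------------------------------------------------- PersonReport

#' Single-subject normative report
#'
#' Per-network raw Pearson correlation (when known), Fisher-Z value,
#' normative z-score in SD units, and a qualitative band. Band cutoffs are
#' provisional conventions of this package (see [personReport()]), not
#' published clinical thresholds.
#'
#' @slot table Data frame with one row per network: `network`, `pearsonR`,
#'   `fisherZ`, `normMean`, `normSd`, `z`, `severity`, `direction`, `band`,
#'   `pctNormal` (normal-approximation percentile) and `pctBand` (position
#'   relative to the empirical 25th-75th percentile band).
#' @slot age Subject age in years (`NA` when unknown).
#' @slot stratum Normative stratum used.
#' @slot cutoffs Numeric length-2 vector: |z| at which a value is flagged
#'   borderline, and abnormal.
#' @export
setClass("PersonReport",
  representation(table = "data.frame", age = "numeric", stratum = "character",
                 cutoffs = "numeric"))

.sdDistancePhrase <- function(z) {
  z1 <- round(z, 1)
  if (z1 == 0) "equal to the normative mean"
  else sprintf("%.1f SD %s the normative mean", abs(z1),
               if (z1 > 0) "above" else "below")
}

setMethod("show", "PersonReport", function(object) {
  cat(sprintf("PersonReport (age %s, stratum '%s')\n",
              if (is.na(object@age)) "unknown" else format(object@age),
              object@stratum))
  cat(sprintf("  band cutoffs |z| >= %.1f borderline, >= %.1f abnormal",
              object@cutoffs[1], object@cutoffs[2]),
      "(provisional, not published clinical thresholds)\n")
  for (i in seq_len(nrow(object@table))) {
    r <- object@table[i, ]
    rtxt <- if (is.na(r$pearsonR)) "" else sprintf("Pearson r = %.2f, ",
                                                   r$pearsonR)
    cat(sprintf("  %-22s %sFisher Z = %.2f; %s (%s)\n", r$network, rtxt,
                r$fisherZ, .sdDistancePhrase(r$z), r$band))
  }
})

## ------------------------------------------------------------------ SimSpec

#' Synthetic-data simulation specification
#'
#' Parameters of the synthetic multi-region BOLD generator: a block
#' correlation structure mirroring the default mode network sub-networks
#' (anterior block, posterior-cingulate block, posterior-to-anterior cross
#' block, background), motion-spike injection, and a subject/session
#' variance decomposition for reliability targeting. Defaults reproduce the
#' study conditions of the normative data: 41 regions of which 14 anterior
#' and 2 posterior-cingulate, five 120-frame task blocks at TR 2.5 s, and
#' block correlations whose Fisher-Z values match the published normative
#' means (anterior 0.63, posterior-to-anterior 0.47, whole-network average
#' approximately 0.39).
#'
#' @slot nRegions,nAnterior,nPcc Node counts.
#' @slot rAnterior,rPcc,rPostAnt,rBackground Target Pearson correlations of
#'   the within-anterior, within-PCC, posterior-to-anterior and background
#'   blocks.
#' @slot nFrames Number of time points. @slot tr Repetition time (s).
#' @slot nSubjects,nSessions Cohort dimensions.
#' @slot metricMean Population mean of the summary metric for cohort panels.
#' @slot sdBetween,sdWithin Between-subject and within-subject SDs of the
#'   subject-level metric shift; the design ICC is
#'   `sdBetween^2 / (sdBetween^2 + sdWithin^2)`.
#' @slot spikeRate Expected fraction of frames carrying a motion spike.
#' @slot spikeMagnitude Translation step size of an injected spike (mm).
#' @slot arCoef Optional AR(1) coefficient for temporal autocorrelation
#'   (default 0, keeping correlation targets exact).
#' @slot seed Integer random seed; same seed gives byte-identical output.
#' @export
setClass("SimSpec",
  representation(nRegions = "integer", nAnterior = "integer", nPcc = "integer",
                 rAnterior = "numeric", rPcc = "numeric", rPostAnt = "numeric",
                 rBackground = "numeric", nFrames = "integer", tr = "numeric",
                 nSubjects = "integer", nSessions = "integer",
                 metricMean = "numeric", sdBetween = "numeric",
                 sdWithin = "numeric", spikeRate = "numeric",
                 spikeMagnitude = "numeric", arCoef = "numeric",
                 seed = "integer"))

setValidity("SimSpec", function(object) {
  rs <- c(object@rAnterior, object@rPcc, object@rPostAnt, object@rBackground)
  if (any(abs(rs) >= 1)) return("target correlations must lie in (-1, 1)")
  if (object@nAnterior + object@nPcc > object@nRegions)
    return("anterior + PCC regions exceed nRegions")
  if (object@spikeRate < 0 || object@spikeRate > 1)
    return("spikeRate must lie in [0, 1]")
  if (object@sdBetween < 0 || object@sdWithin < 0)
    return("variance components must be non-negative")
  if (abs(object@arCoef) >= 1) return("arCoef must lie in (-1, 1)")
  TRUE
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    paste0("SimSpec: %d regions (%d anterior, %d PCC), %d frames @ TR %g s\n",
           "  block r: anterior %.2f, PCC %.2f, post-ant %.2f, background ",
           "%.2f\n  cohort: %d subjects x %d sessions, design ICC %.2f, ",
           "spike rate %.3f, seed %d\n"),
    object@nRegions, object@nAnterior, object@nPcc, object@nFrames,
    object@tr, object@rAnterior, object@rPcc, object@rPostAnt,
    object@rBackground, object@nSubjects, object@nSessions,
    designIcc(object), object@spikeRate, object@seed))
})
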