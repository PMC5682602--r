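#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the classes in this package:
#' `tr()` returns the repetition time in seconds, `regionIds()` the region
#' identifiers, `nFrames()`/`nRegions()` the time-series dimensions,
#' `censorMask()` the [CensorMask-class] attached to a time series,
#' `censored()` the logical censoring vector, `censorReason()` the per-frame
#' provenance, `segmentLabels()` the contiguous segment (quintile) labels,
#' `nFramesUsed()` the number of un-censored frames behind a connectivity
#' matrix, `panelValues()` the subjects-by-conditions matrix of a
#' [MetricPanel-class], `edgeList()` the edge table of a
#' [WeightedGraph-class], and `normEntries()` the data frame inside a
#' [NormTable-class].
#'
#' @param x An object of one of the classes defined in this package.
#' @return The slot value described above.
#' @name accessors
#' @aliases tr regionIds nFrames nRegions censorMask censored censorReason
#'   segmentLabels nFramesUsed panelValues edgeList normEntries
NULL

#' @rdname accessors
#' @export
setGeneric("tr", function(x) standardGeneric("tr"))

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("censorMask", function(x) standardGeneric("censorMask"))

#' @rdname accessors
#' @export
setGeneric("censored", function(x) standardGeneric("censored"))

#' @rdname accessors
#' @export
setGeneric("censorReason", function(x) standardGeneric("censorReason"))

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname accessors
#' @export
setGeneric("nFramesUsed", function(x) standardGeneric("nFramesUsed"))

#' @rdname accessors
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' @rdname accessors
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname accessors
#' @export
setGeneric("normEntries", function(x) standardGeneric("normEntries"))

#' Score an individual against normative connectivity data
#'
#' Generic for [personReport()]; methods exist for named numeric vectors of
#' network averages, [ConnectivityMatrix-class] objects (with sub-network
#' specifications), and [ParcelTimeSeries-class] objects (computing the
#' matrix first).
#'
#' @param object The subject's data (see methods).
#' @param age Age in years, used to select the normative stratum.
#' @param ... Further arguments passed to methods.
#' @return A [PersonReport-class] object.
#' @export
setGeneric("personReport", function(object, age = NA_real_, ...)
  standardGeneric("personReport"))
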