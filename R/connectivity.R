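#' @include AllClasses.R
NULL

#' Fisher Z transform
#'
#' Variance-stabilizing transform of a Pearson correlation,
#' `z = (1/2) log((1 + r) / (1 - r))` (the inverse hyperbolic tangent). Odd
#' and monotone increasing in `r`.
#'
#' @param r Numeric vector of correlations with `|r| < 1`.
#' @param clip When `TRUE`, values with `|r| >= clipLimit` are clipped to
#'   `clipLimit` with a warning instead of raising an error.
#' @param clipLimit Clipping bound (default 0.999999).
#' @return Fisher-Z values (unitless), same length as `r`.
#' @examples
#' fisherZ(c(0.37, 0.62, 0.20))
#' @export
fisherZ <- function(r, clip = FALSE, clipLimit = 0.999999) {
  if (any(!is.finite(r))) stop("non-finite correlation")
  out <- abs(r) >= clipLimit
  if (any(out)) {
    if (!clip)
      stop("correlation magnitude >= 1 is not Fisher-Z transformable ",
           "(set clip = TRUE to clip at ", clipLimit, ")")
    warning(sprintf("%d correlation(s) clipped to |r| = %g", sum(out),
                    clipLimit))
    r <- pmin(pmax(r, -clipLimit), clipLimit)
  }
  atanh(r)
}

#' Pairwise Fisher-Z magnitude connectivity matrix
#'
#' Computes Pearson correlations between the average time courses of every
#' unordered pair of regions in `nodeSet`, using un-censored frames only
#' (one shared listwise mask for all regions, so a single frame count
#' applies to the whole matrix), and stores the magnitude (absolute value)
#' of the Fisher-Z transformed correlation. The diagonal is zero.
#'
#' @param series A [ParcelTimeSeries-class].
#' @param nodeSet Region ids to include (default: all regions). A
#'   [SubNetworkSpec-class] may be given; its node sets are combined.
#' @param clip Passed to [fisherZ()]; near-unity correlations between
#'   (near-)duplicate regions error by default and are clipped when `TRUE`.
#' @return A [ConnectivityMatrix-class].
#' @examples
#' sim <- simulateSubject(simSpec(nRegions = 6, nAnterior = 3, nPcc = 1,
#'                                nFrames = 200, seed = 1))
#' connectivityMatrix(sim$series)
#' @export
connectivityMatrix <- function(series, nodeSet = NULL, clip = FALSE) {
  stopifnot(is(series, "ParcelTimeSeries"))
  if (is(nodeSet, "SubNetworkSpec"))
    nodeSet <- union(nodeSet@nodesA, nodeSet@nodesB)
  ids <- if (is.null(nodeSet)) regionIds(series) else as.character(nodeSet)
  miss <- setdiff(ids, regionIds(series))
  if (length(miss))
    stop("regions not present in the series: ", paste(miss, collapse = ", "))
  keep <- !censored(series)
  if (sum(keep) < 3L) stop("fewer than 3 un-censored frames")
  y <- as.matrix(series)[keep, ids, drop = FALSE]
  sds <- apply(y, 2, stats::sd)
  flat <- ids[sds == 0 | !is.finite(sds)]
  if (length(flat))
    stop("zero variance over un-censored frames in region(s): ",
         paste(flat, collapse = ", "))
  r <- stats::cor(y)
  z <- abs(fisherZ(r[upper.tri(r)], clip = clip))
  m <- matrix(0, length(ids), length(ids))
  m[upper.tri(m)] <- z
  m <- m + t(m)
  ConnectivityMatrix(m, regionIds = ids, nFramesUsed = sum(keep))
}

#' Average connectivity over a sub-network
#'
#' For a within-set specification, the arithmetic mean of the
#' `n (n - 1) / 2` unordered off-diagonal pairs of the node set (each pair
#' counted once, equivalently the mean of the upper triangle). For a
#' between-set specification, the mean over all `|A| x |B|` cross pairs.
#' Units are Fisher-Z magnitudes.
#'
#' @param cm A [ConnectivityMatrix-class].
#' @param spec A [SubNetworkSpec-class]; defaults to the whole matrix
#'   (within-set over all regions).
#' @return Scalar average connectivity.
#' @examples
#' m <- matrix(c(0, .2, .4, .2, 0, .6, .4, .6, 0), 3, 3)
#' averageConnectivity(ConnectivityMatrix(m))  # 0.4
#' @export
averageConnectivity <- function(cm, spec = NULL) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  if (is.null(spec))
    spec <- SubNetworkSpec("whole_matrix", regionIds(cm))
  miss <- setdiff(union(spec@nodesA, spec@nodesB), regionIds(cm))
  if (length(miss))
    stop("sub-network regions missing from the matrix: ",
         paste(miss, collapse = ", "))
  v <- as.matrix(cm)
  rownames(v) <- colnames(v) <- regionIds(cm)
  if (spec@between) {
    vals <- v[spec@nodesA, spec@nodesB, drop = FALSE]
    if (length(vals) < 1L) stop("no eligible region pairs")
    mean(vals)
  } else {
    sub <- v[spec@nodesA, spec@nodesA, drop = FALSE]
    if (length(spec@nodesA) < 2L)
      stop("within-set average requires at least 2 regions")
    mean(sub[upper.tri(sub)])
  }
}
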