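#' @include AllClasses.R
NULL

#' Built-in normative constants for average DMN connectivity
#'
#' Published normative data for average Fisher-Z connectivity of the default
#' mode network and its two sub-networks, from 322 healthy adults, with
#' separate strata for adults aged 50 or younger (n = 253) and over 50
#' (n = 69), reflecting the drop in connectivity after age 50. Values are
#' means, standard deviations and 25th-75th percentile bands in Fisher-Z
#' units.
#'
#' @return A [NormTable-class] with 9 entries (3 networks x 3 strata).
#' @examples
#' normEntries(builtinNorms())
#' @export
builtinNorms <- function() {
  e <- data.frame(
    network = rep(c("whole_dmn", "anterior", "posterior_to_anterior"),
                  each = 3),
    stratum = rep(c("all", "age_le_50", "age_gt_50"), times = 3),
    mean = c(0.39, 0.40, 0.36,  0.63, 0.64, 0.57,  0.47, 0.48, 0.42),
    sd   = c(0.07, 0.07, 0.06,  0.13, 0.13, 0.11,  0.14, 0.14, 0.13),
    p25  = c(0.34, 0.36, 0.32,  0.54, 0.56, 0.49,  0.36, 0.39, 0.31),
    p75  = c(0.43, 0.45, 0.40,  0.71, 0.72, 0.65,  0.57, 0.58, 0.52),
    n    = rep(c(322L, 253L, 69L), times = 3),
    stringsAsFactors = FALSE)
  new("NormTable", entries = e)
}

.selectStratum <- function(age, stratum = NULL) {
  if (!is.null(stratum)) {
    stopifnot(stratum %in% c("all", "age_le_50", "age_gt_50"))
    return(stratum)
  }
  if (is.null(age) || is.na(age)) return("all")
  if (age <= 50) "age_le_50" else "age_gt_50"
}

.normLookup <- function(norms, network, stratum) {
  e <- normEntries(norms)
  row <- e[e$network == network & e$stratum == stratum, ]
  if (nrow(row) != 1L)
    stop("no normative entry for network '", network, "', stratum '",
         stratum, "'")
  row
}

#' Normative z-score of a connectivity value
#'
#' Expresses a Fisher-Z connectivity value in SD units relative to the
#' normative mean of the matching network and age stratum:
#' `z = (value - mean) / sd`. Ages of 50 or less select the `age_le_50`
#' stratum, older ages `age_gt_50`; the pooled `all` stratum can be
#' requested explicitly (and is used when no age is given).
#'
#' @param value Fisher-Z connectivity value.
#' @param network One of `"whole_dmn"`, `"anterior"`,
#'   `"posterior_to_anterior"` (or any network present in `norms`).
#' @param age Age in years (optional if `stratum` given).
#' @param stratum Explicit stratum, overriding age-based selection.
#' @param norms A [NormTable-class] (default [builtinNorms()]).
#' @return The z-score in SD units (exact; reports round to 1 decimal).
#' @examples
#' normativeZ(fisherZ(0.62), "anterior", stratum = "all")   # about +0.7
#' normativeZ(fisherZ(0.20), "posterior_to_anterior", stratum = "all")
#' @export
normativeZ <- function(value, network, age = NULL, stratum = NULL,
                       norms = builtinNorms()) {
  row <- .normLookup(norms, network, .selectStratum(age, stratum))
  (value - row$mean) / row$sd
}

.bandLabel <- function(z, cutoffs) {
  az <- abs(z)
  severity <- if (az < cutoffs[1]) "normal"
    else if (az < cutoffs[2]) "borderline" else "abnormal"
  direction <- if (severity == "normal") "none"
    else if (z < 0) "hypo" else "hyper"
  band <- switch(severity,
                 normal = "within normal limits",
                 borderline = paste0("borderline ", direction,
                                     "-connectivity"),
                 abnormal = paste0(direction, "-connectivity"))
  list(severity = severity, direction = direction, band = band)
}

#' @describeIn personReport Named numeric vector of per-network values.
#'   Names must match networks in the norm table. Values are Fisher-Z by
#'   default; set `pearson = TRUE` when supplying raw Pearson correlations
#'   to transform them first.
#' @param pearson Logical; `TRUE` when `object` holds raw Pearson
#'   correlations.
#' @param stratum Explicit normative stratum overriding age selection.
#' @param norms A [NormTable-class] (default [builtinNorms()]).
#' @param cutoffs Provisional band cutoffs: |z| at which a value is flagged
#'   borderline and abnormal (default `c(1.5, 2)`). These are conventions
#'   of this package, not published clinical thresholds, and are labeled
#'   provisional in all output.
#' @export
setMethod("personReport", signature(object = "numeric"),
  function(object, age = NA_real_, pearson = FALSE, stratum = NULL,
           norms = builtinNorms(), cutoffs = c(1.5, 2), ...) {
    stopifnot(!is.null(names(object)), all(nzchar(names(object))))
    strat <- .selectStratum(if (is.na(age)) NULL else age, stratum)
    rVals <- if (pearson) object else rep(NA_real_, length(object))
    zVals <- if (pearson) fisherZ(object) else object
    rows <- lapply(seq_along(object), function(i) {
      nw <- names(object)[i]
      norm <- .normLookup(norms, nw, strat)
      z <- (zVals[i] - norm$mean) / norm$sd
      b <- .bandLabel(z, cutoffs)
      data.frame(network = nw, pearsonR = rVals[i], fisherZ = zVals[i],
                 normMean = norm$mean, normSd = norm$sd, z = z,
                 severity = b$severity, direction = b$direction,
                 band = b$band,
                 pctNormal = 100 * stats::pnorm(z),
                 pctBand = if (zVals[i] < norm$p25) "below p25"
                           else if (zVals[i] > norm$p75) "above p75"
                           else "within p25-p75",
                 stringsAsFactors = FALSE)
    })
    new("PersonReport", table = do.call(rbind, rows),
        age = as.numeric(age), stratum = strat, cutoffs = cutoffs)
  })

#' @describeIn personReport A [ConnectivityMatrix-class]; the three network
#'   averages are computed from `subnetworks` (as returned by
#'   [deriveSubnetworks()]) and scored.
#' @param subnetworks Named list of [SubNetworkSpec-class] objects.
#' @export
setMethod("personReport", signature(object = "ConnectivityMatrix"),
  function(object, age = NA_real_, subnetworks, stratum = NULL,
           norms = builtinNorms(), cutoffs = c(1.5, 2), ...) {
    vals <- vapply(subnetworks, function(s) averageConnectivity(object, s),
                   numeric(1))
    names(vals) <- vapply(subnetworks, function(s) s@name, character(1))
    personReport(vals, age = age, stratum = stratum, norms = norms,
                 cutoffs = cutoffs)
  })

#' @describeIn personReport A [ParcelTimeSeries-class]; the data-sufficiency
#'   rule is enforced, the connectivity matrix computed over the union of
#'   the sub-network node sets, and the result scored.
#' @param minTotal Overall sufficiency threshold (default 300 frames).
#' @export
setMethod("personReport", signature(object = "ParcelTimeSeries"),
  function(object, age = NA_real_, subnetworks, stratum = NULL,
           norms = builtinNorms(), cutoffs = c(1.5, 2), minTotal = 300,
           ...) {
    suff <- sufficiencyCheck(object, minTotal = minTotal)
    if (!suff$usableOverall)
      stop(sprintf("insufficient data: %d un-censored frames (< %d)",
                   suff$totalUncensored, minTotal))
    ids <- sort(unique(unlist(lapply(subnetworks, function(s)
      union(s@nodesA, s@nodesB)))))
    cm <- connectivityMatrix(object, nodeSet = ids)
    personReport(cm, age = age, subnetworks = subnetworks, stratum = stratum,
                 norms = norms, cutoffs = cutoffs)
  })
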