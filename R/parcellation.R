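#' @include AllClasses.R
NULL

.parcColumns <- c("ParcelID", "Community", "Centroid_x", "Centroid_y",
                  "Centroid_z", "Lobe")

#' Load parcellation metadata
#'
#' Reads a delimited-text region metadata table with one header row and the
#' columns `ParcelID`, `Community`, `Centroid_x`, `Centroid_y`, `Centroid_z`,
#' `Lobe`. Coordinates are in standard-space millimetres with `x` signed and
#' 0 at the midline. Network membership is taken from the `Community` column
#' (the default mode network is labeled `"Default"`); anatomical membership
#' (frontal lobe, posterior cingulate) is taken from the `Lobe` column
#' rather than recomputed from an atlas.
#'
#' When `scheme = "cortical333"` the table is additionally validated against
#' the reference 333-region cortical parcellation: 333 regions, 41 labeled
#' `Default`, of which 14 form the anterior (frontal midline) set and 2 the
#' posterior-cingulate set. Arbitrary parcellations use
#' `scheme = "generic"` and skip these count checks.
#'
#' @param path Path to the delimited text file.
#' @param sep Field separator (default `"\t"`; `","` for CSV).
#' @param scheme `"generic"` (no count validation) or `"cortical333"`.
#' @return A data frame of validated region records (one row per region)
#'   with an attribute `nDefault` giving the count of `Default`-labeled
#'   regions, also reported via a message.
#' @seealso [deriveSubnetworks()], [syntheticParcellation()]
#' @export
loadParcellation <- function(path, sep = "\t",
                             scheme = c("generic", "cortical333")) {
  scheme <- match.arg(scheme)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validateParcellation(tab, scheme = scheme)
}

#' Validate a parcellation metadata table
#'
#' @param tab Data frame with the columns listed in [loadParcellation()].
#' @param scheme See [loadParcellation()].
#' @return The validated data frame (ids coerced to character) with
#'   attribute `nDefault`.
#' @export
validateParcellation <- function(tab, scheme = c("generic", "cortical333")) {
  scheme <- match.arg(scheme)
  missing <- setdiff(.parcColumns, names(tab))
  if (length(missing))
    stop("parcellation table is missing columns: ",
         paste(missing, collapse = ", "))
  cc <- c("Centroid_x", "Centroid_y", "Centroid_z")
  for (col in cc) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite %s at row(s) %s", col,
                   paste(bad, collapse = ", ")))
    tab[[col]] <- v
  }
  tab$ParcelID <- as.character(tab$ParcelID)
  dup <- unique(tab$ParcelID[duplicated(tab$ParcelID)])
  if (length(dup))
    stop("duplicate region id(s): ", paste(dup, collapse = ", "))
  nDefault <- sum(tab$Community == "Default")
  message(sprintf("parcellation: %d regions, %d labeled Default",
                  nrow(tab), nDefault))
  if (scheme == "cortical333") {
    if (nrow(tab) != 333L)
      stop("cortical333 scheme expects 333 regions, got ", nrow(tab))
    if (nDefault != 41L)
      stop("cortical333 scheme expects 41 Default regions, got ", nDefault)
  }
  attr(tab, "nDefault") <- nDefault
  attr(tab, "scheme") <- scheme
  tab
}

#' Derive the DMN node set and its geometric sub-networks
#'
#' From validated region metadata, builds the three canonical sub-network
#' specifications:
#' \describe{
#'   \item{whole_dmn}{all `Default`-community regions (within-set).}
#'   \item{anterior}{`Default` regions in the frontal lobe whose centroid
#'     lies within `midlineMm` of the midline, i.e. `|Centroid_x| <=
#'     midlineMm` (inclusive boundary); within-set.}
#'   \item{posterior_to_anterior}{`Default` regions whose `Lobe` label marks
#'     posterior-cingulate membership, crossed with the anterior set
#'     (between-set).}
#' }
#' The result is deterministic and independent of input row order (node
#' sets are sorted by region id).
#'
#' For the reference 333-region scheme (`scheme` attribute
#' `"cortical333"`), the derived sets are checked against the published
#' counts: 14 anterior regions and 2 posterior-cingulate regions.
#'
#' @param regions Data frame from [loadParcellation()] /
#'   [validateParcellation()].
#' @param midlineMm Midline distance criterion in mm (default 15,
#'   inclusive).
#' @param frontalLabel `Lobe` value marking frontal regions (default
#'   `"Frontal"`).
#' @param pccLabel `Lobe` value marking posterior-cingulate regions
#'   (default `"PCC"`).
#' @param network Community label of the network of interest (default
#'   `"Default"`).
#' @return Named list of three [SubNetworkSpec-class] objects:
#'   `whole_dmn`, `anterior`, `posterior_to_anterior`.
#' @examples
#' parc <- syntheticParcellation()
#' subs <- deriveSubnetworks(parc)
#' lengths(list(dmn = subs$whole_dmn@nodesA, ant = subs$anterior@nodesA))
#' @export
deriveSubnetworks <- function(regions, midlineMm = 15,
                              frontalLabel = "Frontal", pccLabel = "PCC",
                              network = "Default") {
  stopifnot(all(.parcColumns %in% names(regions)), midlineMm >= 0)
  dmn <- regions[regions$Community == network, , drop = FALSE]
  if (nrow(dmn) == 0L)
    stop("no regions labeled '", network, "' in the parcellation")
  antSel <- dmn$Lobe == frontalLabel & abs(dmn$Centroid_x) <= midlineMm
  pccSel <- dmn$Lobe == pccLabel
  antIds <- sort(dmn$ParcelID[antSel])
  pccIds <- sort(dmn$ParcelID[pccSel])
  if (length(antIds) == 0L)
    stop("anterior sub-network is empty (no frontal midline regions)")
  if (length(pccIds) == 0L)
    stop("posterior-to-anterior sub-network is undefined (no PCC regions)")
  if (length(intersect(antIds, pccIds)))
    stop("anterior and PCC sets overlap; check the Lobe labels")
  if (identical(attr(regions, "scheme"), "cortical333")) {
    if (length(antIds) != 14L)
      stop("cortical333 scheme expects 14 anterior regions, got ",
           length(antIds))
    if (length(pccIds) != 2L)
      stop("cortical333 scheme expects 2 PCC regions, got ", length(pccIds))
  }
  list(
    whole_dmn = SubNetworkSpec("whole_dmn", sort(dmn$ParcelID)),
    anterior = SubNetworkSpec("anterior", antIds),
    posterior_to_anterior = SubNetworkSpec("posterior_to_anterior",
                                           pccIds, antIds, between = TRUE))
}
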