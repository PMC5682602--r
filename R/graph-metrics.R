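#' @include AllClasses.R
NULL

#' Proportional edge thresholding
#'
#' Converts a connectivity matrix into a non-directed weighted graph keeping
#' the `ceiling(retain * m)` strongest of the `m = n (n - 1) / 2` possible
#' edges and zeroing the rest. Ties exactly at the cut weight are broken by
#' lexicographic node-pair order, so the result is deterministic and the
#' retained edge count always equals `ceiling(retain * m)` (edges whose
#' weight is exactly zero are dropped, as a zero-weight edge is no edge).
#' Retention fractions of 0.70, 0.75 and 0.80 are the conventional choices;
#' 70% is typically the smallest fraction leaving every node at least one
#' edge. A warning is emitted when any node is isolated after thresholding.
#'
#' @param cm A [ConnectivityMatrix-class].
#' @param retain Fraction of possible edges to keep, in (0, 1].
#' @return A [WeightedGraph-class]; its `isolatedNodes` and `connected`
#'   slots report whether every node kept at least one edge and whether the
#'   graph is connected.
#' @examples
#' sim <- simulateSubject(simSpec(nRegions = 8, nAnterior = 3, nPcc = 1,
#'                                nFrames = 300, seed = 7))
#' proportionalThreshold(connectivityMatrix(sim$series), 0.70)
#' @export
proportionalThreshold <- function(cm, retain = 0.70) {
  stopifnot(is(cm, "ConnectivityMatrix"), retain > 0, retain <= 1)
  ids <- regionIds(cm)
  n <- length(ids)
  v <- as.matrix(cm)
  iu <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[iu]
  m <- nrow(iu)
  k <- ceiling(retain * m)
  ord <- order(-w, iu[, 1], iu[, 2])
  sel <- ord[seq_len(k)]
  sel <- sel[w[sel] > 0]
  edges <- data.frame(from = ids[iu[sel, 1]], to = ids[iu[sel, 2]],
                      weight = w[sel], stringsAsFactors = FALSE)
  g <- WeightedGraph(ids, edges, retention = retain)
  if (length(g@isolatedNodes))
    warning(sprintf("%d node(s) isolated at retention %.0f%%: %s",
                    length(g@isolatedNodes), 100 * retain,
                    paste(g@isolatedNodes, collapse = ", ")))
  g
}

.weightMatrix <- function(g) {
  ids <- g@nodes
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- g@edges
  if (nrow(e)) {
    w[cbind(e$from, e$to)] <- e$weight
    w[cbind(e$to, e$from)] <- e$weight
  }
  w
}

#' Weighted global clustering coefficient
#'
#' Weighted transitivity of the graph: the sum of triplet values over
#' closed triplets (the two anchoring edges of the triplet plus the edge
#' closing the triangle) divided by the sum over all triplets. A triplet is
#' a center node with an unordered pair of neighbors, and its value is by
#' default the arithmetic mean of the two anchoring edge weights; `min`,
#' `max` and geometric-mean variants are available. Captures the
#' short-range efficiency of a network: the probability that two regions
#' strongly connected to a third are also connected to each other.
#'
#' With the arithmetic triplet value the coefficient is invariant to a
#' common positive rescaling of all weights and lies in [0, 1].
#'
#' @param g A [WeightedGraph-class].
#' @param tripletValue How a triplet's two anchoring weights are combined:
#'   `"arithmetic"` (default), `"min"`, `"max"` or `"geometric"`.
#' @return Scalar clustering coefficient in [0, 1].
#' @examples
#' tri <- WeightedGraph(c("a", "b", "c"),
#'   data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
#'              weight = c(1, 1, 1)))
#' globalClustering(tri)  # 1
#' @export
globalClustering <- function(g, tripletValue = c("arithmetic", "min", "max",
                                                 "geometric")) {
  stopifnot(is(g, "WeightedGraph"))
  tripletValue <- match.arg(tripletValue)
  w <- .weightMatrix(g)
  b <- (w > 0) * 1
  if (max(rowSums(b)) < 2)
    stop("graph has no triplets (no node with two or more neighbors)")
  if (tripletValue == "arithmetic") {
    # closed triplets: sum over ordered (i, j) of w_ij * |common nbrs of i, j|
    cn <- b %*% b
    num <- sum(w * cn) / 2
    den <- sum((rowSums(b) - 1) * rowSums(w)) / 2
    return(num / den)
  }
  comb <- switch(tripletValue, min = pmin, max = pmax,
                 geometric = function(a, b) sqrt(a * b))
  num <- 0
  den <- 0
  for (i in seq_len(nrow(w))) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2)
    val <- comb(w[i, prs[1, ]], w[i, prs[2, ]])
    den <- den + sum(val)
    closed <- w[cbind(prs[1, ], prs[2, ])] > 0
    num <- num + sum(val[closed])
  }
  num / den
}

#' Weighted characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs, where
#' traversing an edge of weight `w` costs `w^-alpha` (default `alpha = 1`,
#' i.e. cost = 1 / weight, so strong connections are short). Captures the
#' long-range efficiency of a network. On a disconnected graph the mean is
#' taken over reachable pairs and the number of unreachable pairs is
#' attached as attribute `nUnreachablePairs` (with a warning); an error is
#' raised only when no pair is reachable.
#'
#' @param g A [WeightedGraph-class].
#' @param alpha Exponent of the weight-to-cost transform (default 1).
#' @return Scalar mean shortest-path cost with attribute
#'   `nUnreachablePairs`.
#' @examples
#' two <- WeightedGraph(c("a", "b"),
#'   data.frame(from = "a", to = "b", weight = 0.5))
#' characteristicPathLength(two)  # 2
#' @export
characteristicPathLength <- function(g, alpha = 1) {
  stopifnot(is(g, "WeightedGraph"), alpha > 0)
  if (nrow(g@edges) == 0L) stop("graph has no edges; all pairs unreachable")
  ig <- .asIgraph(g@nodes, g@edges)
  d <- igraph::distances(ig, weights = igraph::E(ig)$weight^(-alpha))
  du <- d[upper.tri(d)]
  reach <- is.finite(du)
  if (!any(reach)) stop("all node pairs unreachable")
  nUnreach <- sum(!reach)
  if (nUnreach > 0)
    warning(sprintf("%d unordered pair(s) unreachable; averaging over %d reachable pair(s)",
                    nUnreach, sum(reach)))
  structure(mean(du[reach]), nUnreachablePairs = nUnreach)
}
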