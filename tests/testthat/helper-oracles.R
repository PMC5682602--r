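# Independent oracles and small fixture builders, kept deliberately naive.

# Brute-force weighted transitivity: enumerate every (center, neighbor-pair)
# triplet explicitly.
bruteClustering <- function(g, comb = function(a, b) (a + b) / 2) {
  ids <- g@nodes
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- edgeList(g)
  for (r in seq_len(nrow(e))) {
    w[e$from[r], e$to[r]] <- e$weight[r]
    w[e$to[r], e$from[r]] <- e$weight[r]
  }
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j >= k || j == i || k == i) next
    if (w[i, j] > 0 && w[i, k] > 0) {
      v <- comb(w[i, j], w[i, k])
      den <- den + v
      if (w[j, k] > 0) num <- num + v
    }
  }
  if (den == 0) stop("no triplets")
  num / den
}

# Floyd-Warshall all-pairs shortest paths on inverse-weight costs, then the
# mean over reachable unordered pairs.
brutePathLength <- function(g, alpha = 1) {
  ids <- g@nodes
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  e <- edgeList(g)
  for (r in seq_len(nrow(e))) {
    cost <- e$weight[r]^(-alpha)
    d[e$from[r], e$to[r]] <- min(d[e$from[r], e$to[r]], cost)
    d[e$to[r], e$from[r]] <- min(d[e$to[r], e$from[r]], cost)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  du <- d[upper.tri(d)]
  mean(du[is.finite(du)])
}

# Random weighted graph on <= maxNodes nodes with at least one triplet.
randomGraph <- function(maxNodes = 8, pEdge = 0.6) {
  repeat {
    n <- sample(3:maxNodes, 1)
    ids <- paste0("n", seq_len(n))
    prs <- utils::combn(ids, 2)
    keep <- stats::runif(ncol(prs)) < pEdge
    if (sum(keep) < 2) next
    e <- data.frame(from = prs[1, keep], to = prs[2, keep],
                    weight = round(stats::runif(sum(keep), 0.05, 1), 3),
                    stringsAsFactors = FALSE)
    g <- WeightedGraph(ids, e)
    deg <- table(factor(c(e$from, e$to), levels = ids))
    if (max(deg) >= 2) return(g)
  }
}

# Tiny parcellation table used across parcellation tests.
toyParcellation <- function() {
  data.frame(
    ParcelID = 1:5,
    Community = c("Default", "Default", "Default", "Visual", "Visual"),
    Centroid_x = c(0, 10, -20, 30, -30),
    Centroid_y = c(50, 45, -50, -80, -80),
    Centroid_z = c(10, 20, 30, 0, 0),
    Lobe = c("Frontal", "Frontal", "PCC", "Occipital", "Occipital"),
    stringsAsFactors = FALSE)
}

# Series whose five segments are exact copies of one block.
replicatedSegmentSeries <- function(block, tr = 2.5) {
  x <- do.call(rbind, rep(list(block), 5))
  ParcelTimeSeries(x, tr = tr, segmentLabels = makeSegmentLabels(nrow(x), 5))
}
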