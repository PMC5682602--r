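makeCm <- function(w, ids = NULL) {
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(w)))
  ConnectivityMatrix(w, regionIds = ids)
}

test_that("proportional thresholding keeps ceiling(retain * m) strongest edges", {
  set.seed(21)
  n <- 5
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- sample(seq(0.1, 1, length.out = 10))
  w <- w + t(w)
  cm <- makeCm(w)
  g1 <- proportionalThreshold(cm, 1)
  expect_equal(nrow(edgeList(g1)), 10L)             # full support retained
  expect_equal(sort(edgeList(g1)$weight), sort(w[upper.tri(w)]))
  g7 <- proportionalThreshold(cm, 0.70)
  expect_equal(nrow(edgeList(g7)), 7L)              # ceiling(0.7 * 10)
  expect_equal(sort(edgeList(g7)$weight, decreasing = TRUE),
               sort(w[upper.tri(w)], decreasing = TRUE)[1:7])
})

test_that("ties at the cut weight break deterministically with exact edge count", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.9, 0.5, 0.5, 0.5, 0.5, 0.2)   # 4-way tie at 0.5
  w <- w + t(w)
  cm <- makeCm(w)
  g <- proportionalThreshold(cm, 0.5)                  # keep 3 of 6
  expect_equal(nrow(edgeList(g)), 3L)
  g2 <- proportionalThreshold(cm, 0.5)
  expect_identical(edgeList(g), edgeList(g2))          # deterministic
})

test_that("the canonical retentions yield nested edge sets and isolation warns", {
  set.seed(22)
  n <- 10
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, 0.01, 1)
  w <- w + t(w)
  cm <- makeCm(w)
  key <- function(g) paste(edgeList(g)$from, edgeList(g)$to)
  k70 <- key(proportionalThreshold(cm, 0.70))
  k75 <- key(proportionalThreshold(cm, 0.75))
  k80 <- key(proportionalThreshold(cm, 0.80))
  expect_true(all(k70 %in% k75) && all(k75 %in% k80))
  # a node whose edges are all weakest becomes isolated at low retention
  w2 <- matrix(0.9, 4, 4); diag(w2) <- 0
  w2[4, 1:3] <- w2[1:3, 4] <- 0.01
  expect_warning(proportionalThreshold(makeCm(w2), 0.5), "isolated")
})

test_that("clustering is 1 on a triangle, 0 on a path, and exact on the hand example", {
  tri <- WeightedGraph(c("a", "b", "c"),
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               weight = c(0.3, 0.3, 0.3)))
  expect_equal(globalClustering(tri), 1)
  path <- WeightedGraph(c("a", "b", "c"),
    data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(1, 1)))
  expect_equal(globalClustering(path), 0)
  g4 <- WeightedGraph(paste0("n", 1:4),
    data.frame(from = c("n1", "n1", "n2", "n3"),
               to = c("n2", "n3", "n3", "n4"),
               weight = c(0.4, 0.6, 0.2, 0.8)))
  expect_equal(globalClustering(g4), 0.5)              # brute-force value
  expect_equal(globalClustering(g4), bruteClustering(g4))
  single <- WeightedGraph(c("a", "b"),
    data.frame(from = "a", to = "b", weight = 1))
  expect_error(globalClustering(single), "no triplets")
})

test_that("all triplet-value variants match brute-force enumeration on random graphs", {
  set.seed(23)
  combs <- list(arithmetic = function(a, b) (a + b) / 2,
                min = pmin, max = pmax,
                geometric = function(a, b) sqrt(a * b))
  for (i in 1:40) {
    g <- randomGraph()
    for (nm in names(combs)) {
      expect_equal(globalClustering(g, tripletValue = nm),
                   bruteClustering(g, combs[[nm]]),
                   tolerance = 1e-12, label = sprintf("graph %d, %s", i, nm))
    }
  }
})

test_that("path length inverts weights and matches Floyd-Warshall", {
  two <- WeightedGraph(c("a", "b"),
    data.frame(from = "a", to = "b", weight = 0.5))
  expect_equal(as.numeric(characteristicPathLength(two)), 2)   # 1 / 0.5
  compl <- WeightedGraph(c("a", "b", "c"),
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               weight = c(1, 1, 1)))
  expect_equal(as.numeric(characteristicPathLength(compl)), 1)
  # triangle with a weak direct edge: detour through the middle is shorter
  tri <- WeightedGraph(c("1", "2", "3"),
    data.frame(from = c("1", "2", "1"), to = c("2", "3", "3"),
               weight = c(0.5, 0.5, 0.2)))
  expect_equal(as.numeric(characteristicPathLength(tri)), 8 / 3)
  set.seed(24)
  for (i in 1:40) {
    g <- randomGraph()
    # sparse draws may be disconnected; both routes average reachable pairs
    expect_equal(as.numeric(suppressWarnings(characteristicPathLength(g))),
                 brutePathLength(g), tolerance = 1e-12,
                 label = paste("graph", i))
  }
})

test_that("disconnected graphs average reachable pairs and report the rest", {
  g <- WeightedGraph(c("a", "b", "c", "d"),
    data.frame(from = c("a", "c"), to = c("b", "d"), weight = c(0.5, 0.25)))
  expect_warning(L <- characteristicPathLength(g), "unreachable")
  expect_equal(as.numeric(L), (2 + 4) / 2)
  expect_equal(attr(L, "nUnreachablePairs"), 4L)
  empty <- WeightedGraph(c("a", "b"),
                         data.frame(from = character(0), to = character(0),
                                    weight = numeric(0)))
  expect_error(characteristicPathLength(empty), "unreachable")
})

test_that("rescaling weights leaves clustering invariant and divides path length", {
  set.seed(25)
  g <- randomGraph()
  e <- edgeList(g)
  e$weight <- e$weight * 3.7
  g2 <- WeightedGraph(g@nodes, e)
  expect_equal(globalClustering(g2), globalClustering(g), tolerance = 1e-12)
  expect_equal(as.numeric(characteristicPathLength(g2)),
               as.numeric(characteristicPathLength(g)) / 3.7,
               tolerance = 1e-12)
  # the alpha exponent maps weights to costs as weight^-alpha
  expect_equal(as.numeric(characteristicPathLength(g, alpha = 2)),
               brutePathLength(g, alpha = 2), tolerance = 1e-12)
})
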