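handPanel43 <- function() {
  MetricPanel(matrix(c(1, 2, 3,
                       2, 4, 5,
                       3, 5, 7,
                       4, 7, 9), nrow = 4, byrow = TRUE))
}

handPanel42 <- function() {
  MetricPanel(matrix(c(9, 10,
                       6, 5,
                       8, 7,
                       2, 4), nrow = 4, byrow = TRUE))
}

test_that("quintile metrics are computed per contiguous segment", {
  set.seed(31)
  block <- matrix(rnorm(120 * 4), 120, 4) %*%
    chol(0.6 + 0.4 * diag(4))
  pts <- replicatedSegmentSeries(block)
  est <- quintileMetrics(pts)
  expect_length(est, 5L)
  expect_true(all(est == est[1]))        # identical segments, identical values
  # a stationary series gives five estimates within sampling error
  sim <- simulateSubject(simSpec(seed = 32))
  est2 <- quintileMetrics(sim$series, sim$subnetworks$whole_dmn)
  expect_lt(max(est2) - min(est2), 0.15)
})

test_that("a 99-frame quintile excludes the subject from the panel", {
  sim <- simulateSubject(simSpec(seed = 33, spikeRate = 0))
  cen <- rep(FALSE, 600); cen[1:21] <- TRUE         # quintile 1 drops to 99
  pts <- applyCensorMask(sim$series, CensorMask(cen))
  expect_error(quintileMetrics(pts), class = "insufficientSegmentData")
  ok <- simulateSubject(simSpec(seed = 34, spikeRate = 0))$series
  panel <- quintilePanel(list(A = ok, B = pts, C = ok, D = ok),
                         spec = sim$subnetworks$whole_dmn)
  expect_identical(attr(panel, "excluded"), "B")
  expect_equal(nrow(panelValues(panel)), 3L)
})

test_that("Cronbach's alpha matches the hand-evaluated formula and identity case", {
  a <- cronbachAlpha(handPanel43())
  # var_i = {5/3, 13/3, 20/3}, var_total = 106/3:
  # alpha = 3/2 * (1 - 38/106) = 51/53
  expect_equal(a@estimate, 51 / 53, tolerance = 1e-12)
  expect_true(a@ciLow <= a@estimate && a@estimate <= a@ciHigh)
  # replicate columns: alpha = 1
  same <- MetricPanel(matrix(rep(c(1, 5, 2, 4), 3), ncol = 3))
  expect_equal(cronbachAlpha(same)@estimate, 1)
  # zero variance across subjects is undefined
  expect_error(cronbachAlpha(MetricPanel(matrix(1, 4, 3))), "variance")
})

test_that("alpha of independent columns is near zero and invariances hold", {
  set.seed(35)
  v <- matrix(rnorm(2000 * 2), 2000, 2)
  expect_lt(abs(cronbachAlpha(MetricPanel(v))@estimate), 0.1)
  p <- handPanel43()
  # invariant to a per-condition constant and a common positive rescaling
  shifted <- MetricPanel(sweep(panelValues(p), 2, c(10, -3, 0.5), "+"))
  scaled <- MetricPanel(panelValues(p) * 7)
  expect_equal(cronbachAlpha(shifted)@estimate, cronbachAlpha(p)@estimate)
  expect_equal(cronbachAlpha(scaled)@estimate, cronbachAlpha(p)@estimate)
})

test_that("agreement ICC matches the hand ANOVA table and the aov decomposition", {
  p <- handPanel42()
  r <- iccAgreement(p)
  # MSR = 371/24, MSC = 1/8, MSE = 9/8 ->
  # ICC = (MSR - MSE) / (MSR + MSE + (2/4)(MSC - MSE)) = 172/193
  expect_equal(r@estimate, 172 / 193, tolerance = 1e-12)
  # cross-check mean squares against stats::aov
  v <- panelValues(p)
  fit <- stats::aov(val ~ subj + sess,
                    data = data.frame(val = as.vector(v),
                                      subj = factor(rep(1:4, 2)),
                                      sess = factor(rep(1:2, each = 4))))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  icc <- (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / 4) * (ms[2] - ms[3]))
  expect_equal(r@estimate, icc)
  expect_true(r@ciLow <= r@estimate && r@estimate <= r@ciHigh)
})

test_that("ICC identity, range, and offset-penalty properties hold", {
  v <- matrix(c(3, 7, 5, 9, 1, 4), 6, 2)            # session 2 == session 1
  r <- iccAgreement(MetricPanel(cbind(v[, 1], v[, 1])))
  expect_equal(r@estimate, 1)
  expect_true(r@degenerate)
  set.seed(36)
  b <- rnorm(200)
  panel <- cbind(b + rnorm(200, 0, 0.6), b + rnorm(200, 0, 0.6))
  agree <- iccAgreement(MetricPanel(panel))
  expect_gte(agree@estimate, -1)
  expect_lte(agree@estimate, 1)
  # constant session offset: agreement drops strictly below consistency
  off <- panel; off[, 2] <- off[, 2] + 1
  expect_lt(iccAgreement(MetricPanel(off))@estimate,
            iccAgreement(MetricPanel(off), type = "consistency")@estimate)
})

test_that("ICC recovers the generative intraclass correlation 0.62", {
  set.seed(37)
  rho <- 0.62
  b <- rnorm(500, 0, sqrt(rho))
  v <- b + matrix(rnorm(1000, 0, sqrt(1 - rho)), 500, 2)
  expect_lt(abs(iccAgreement(MetricPanel(v))@estimate - rho), 0.05)
})

test_that("replication requires equal means and alpha inside the reference CI", {
  set.seed(38)
  x <- rnorm(50, 0.39, 0.07)
  same <- replicationCheck(list(s1 = x, s2 = x, s3 = x))
  expect_true(same$meansReplicated)
  mkRel <- function(est, lo, hi)
    new("ReliabilityResult", estimate = est, ciLow = lo, ciHigh = hi,
        kind = "cronbach_alpha", nSubjects = 50L, nConditions = 5L,
        degenerate = FALSE)
  # alpha 0.74 against reference CI [0.41, 0.68]: not replicated
  out <- replicationCheck(list(s1 = x, s3 = x + rnorm(50, 0, 1e-6)),
                          list(mkRel(0.55, 0.41, 0.68), mkRel(0.74, 0.6, 0.85)))
  expect_false(out$reliabilityReplicated[["s3"]])
  out2 <- replicationCheck(list(s1 = x, s2 = x),
                           list(mkRel(0.55, 0.41, 0.68), mkRel(0.6, 0.5, 0.7)))
  expect_true(out2$reliabilityReplicated[["s2"]])
  # shifted means break replication
  shift <- replicationCheck(list(s1 = x, s2 = x + 1))
  expect_false(shift$meansReplicated)
})

test_that("same-distribution samples replicate in at least 90% of seeded runs", {
  set.seed(39)
  hits <- 0L
  for (i in 1:200) {
    samples <- replicate(3, rnorm(40, 0.39, 0.07), simplify = FALSE)
    if (replicationCheck(samples)$meansReplicated) hits <- hits + 1L
  }
  expect_gte(hits, 180L)
})
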