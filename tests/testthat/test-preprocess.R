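test_that("framewise displacement sums absolute differentiated parameters", {
  expect_equal(framewiseDisplacement(matrix(0, 10, 6)), rep(0, 10))
  rp <- matrix(0, 10, 6)
  rp[5:10, 1] <- 0.1                       # one 0.1 mm x-translation step
  expect_equal(framewiseDisplacement(rp), c(rep(0, 4), 0.1, rep(0, 5)))
  # translations (0.05, 0.05, 0.05) mm plus 0.001 rad rotation on a 50 mm
  # sphere: 0.15 + 0.05 = 0.20
  rp2 <- matrix(0, 3, 6)
  rp2[2:3, 1:3] <- 0.05
  rp2[2:3, 4] <- 0.001
  expect_equal(framewiseDisplacement(rp2)[2], 0.20)
  expect_equal(framewiseDisplacement(rp2, rotationRadiusMm = 100)[2], 0.25)
  expect_error(framewiseDisplacement(matrix(0, 1, 6)), "at least 2 frames")
})

test_that("scaled intensity difference is the mean squared step over the grand mean", {
  expect_equal(scaledIntensityDiff(rep(7, 50)), rep(0, 50))
  d <- scaledIntensityDiff(c(10, 10, 30, 10))   # grand mean 15
  expect_equal(d, c(0, 0, 400 / 15, 400 / 15))
  expect_gt(max(d), 10)                          # would be censored
  expect_error(scaledIntensityDiff(c(-5, 5)), "grand mean")
})

test_that("one isolated spike censors four frames; boundaries clip", {
  fd <- rep(0, 120)
  m0 <- buildCensorMask(fd, NULL)
  expect_false(any(censored(m0)))
  fd[11] <- 0.5                                  # spike at t = 11
  m <- buildCensorMask(fd, NULL)
  expect_identical(which(censored(m)), 10:13)    # {t-1, t, t+1, t+2}
  expect_equal(sum(censored(m)), 4L)
  expect_equal(censorReason(m)[11], "motion")
  expect_setequal(censorReason(m)[c(10, 12, 13)], "expansion")
  fd0 <- rep(0, 120); fd0[1] <- 0.4              # spike at the first frame
  expect_identical(which(censored(buildCensorMask(fd0, NULL))), 1:3)
  # two-frame variant
  m2 <- buildCensorMask(fd, NULL, expand = "two")
  expect_identical(which(censored(m2)), 11:12)
})

test_that("overlapping expansions merge, intensity spikes are labeled, censoring is idempotent", {
  fd <- rep(0, 60); fd[c(10, 12)] <- 1
  m <- buildCensorMask(fd, NULL)
  expect_identical(which(censored(m)), 9:14)
  sid <- rep(0, 60); sid[30] <- 11
  mi <- buildCensorMask(rep(0, 60), sid)
  expect_equal(censorReason(mi)[30], "intensity")
  expect_identical(which(censored(mi)), 29:32)
  # idempotence: the mask is a pure function of the spike vectors
  expect_identical(censored(buildCensorMask(fd, sid)),
                   censored(buildCensorMask(fd, sid)))
  # expansion does not cross segment boundaries when labels are supplied
  segs <- rep(1:2, each = 30)
  fd2 <- rep(0, 60); fd2[30] <- 1
  mseg <- buildCensorMask(fd2, NULL, segments = segs)
  expect_identical(which(censored(mseg)), 29:30)
})

test_that("residualization is an OLS projection", {
  set.seed(41)
  y <- matrix(rnorm(200 * 3), 200, 3)
  pts <- ParcelTimeSeries(y, tr = 2.5)
  centered <- residualize(pts)                   # intercept only
  expect_equal(as.matrix(centered), scale(y, scale = FALSE),
               ignore_attr = TRUE)
  tt <- seq_len(200)
  conf <- cbind(sin(2 * pi * tt / 40))
  # a series equal to the confound residualizes to zero
  same <- ParcelTimeSeries(cbind(3 * conf + 5), tr = 2.5)
  expect_lt(max(abs(as.matrix(residualize(same, conf)))), 1e-10)
  # residuals orthogonal to the confound
  res <- residualize(pts, conf)
  expect_lt(max(abs(crossprod(as.matrix(res), conf))), 1e-8)
  # projection: applying twice equals applying once
  expect_equal(as.matrix(residualize(res, conf)), as.matrix(res),
               tolerance = 1e-12)
  # collinear confounds are dropped with a warning
  expect_warning(residualize(pts, cbind(conf, 2 * conf)), "collinear")
  # censored frames get exact-zero residuals via indicator regressors
  cen <- CensorMask(tt %in% 50:53)
  resc <- residualize(applyCensorMask(pts, cen), conf)
  expect_equal(as.matrix(resc)[50:53, ], matrix(0, 4, 3),
               ignore_attr = TRUE)
})

test_that("band-pass keeps the pass band, removes DC and stop band, and is linear", {
  n <- 600; trs <- 2.5
  tt <- (seq_len(n) - 1) * trs
  keepWave <- sin(2 * pi * 0.04 * tt)
  stopWave <- sin(2 * pi * 0.15 * tt)
  x <- cbind(keepWave, stopWave, rep(4, n), keepWave + stopWave)
  colnames(x) <- NULL
  pts <- ParcelTimeSeries(x, tr = trs)
  out <- as.matrix(bandpass(pts))
  amp <- function(x) sqrt(mean(x^2))
  expect_gt(amp(out[, 1]) / amp(keepWave), 0.95)      # 0.04 Hz preserved
  expect_lt(amp(out[, 2]) / amp(stopWave), 0.10)      # 0.15 Hz attenuated
  expect_lt(amp(out[, 3]), 1e-8)                      # DC removed
  expect_equal(out[, 4], out[, 1] + out[, 2], tolerance = 1e-8)  # linearity
  expect_error(bandpass(pts, high = 0.25), "Nyquist")
})

test_that("sufficiency thresholds are 300 overall and 100 per quintile", {
  ok <- sufficiencyCheck(CensorMask(rep(FALSE, 600)))
  expect_true(ok$usableOverall)
  expect_true(ok$usableSegments)
  expect_equal(ok$totalUncensored, 600L)
  # 301 of 600 censored leaves 299 < 300
  m299 <- CensorMask(seq_len(600) <= 301)
  expect_false(sufficiencyCheck(m299)$usableOverall)
  # one quintile at 99 un-censored fails segments but not the overall rule
  cen <- rep(FALSE, 600); cen[1:21] <- TRUE            # quintile 1: 99 left
  s <- sufficiencyCheck(CensorMask(cen))
  expect_false(s$usableSegments)
  expect_true(s$usableOverall)
  expect_equal(s$segmentCounts, c(99L, 120L, 120L, 120L, 120L))
})
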