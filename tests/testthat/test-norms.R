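test_that("built-in norms hold the nine published entries", {
  e <- normEntries(builtinNorms())
  expect_equal(nrow(e), 9L)                      # 3 networks x 3 strata
  pick <- function(nw, st) e[e$network == nw & e$stratum == st, ]
  wd <- pick("whole_dmn", "all")
  expect_equal(c(wd$mean, wd$sd), c(0.39, 0.07))
  expect_equal(c(wd$p25, wd$p75, wd$n), c(0.34, 0.43, 322))
  ag <- pick("anterior", "age_gt_50")
  expect_equal(c(ag$mean, ag$sd), c(0.57, 0.11))
  # strata sizes are consistent: 253 + 69 = 322
  expect_equal(pick("whole_dmn", "age_le_50")$n +
                 pick("whole_dmn", "age_gt_50")$n,
               pick("whole_dmn", "all")$n)
  # connectivity drops after age 50 in every network
  for (nw in unique(e$network))
    expect_gt(pick(nw, "age_le_50")$mean, pick(nw, "age_gt_50")$mean)
})

test_that("norm tables round-trip through text bit-exactly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeNorms(builtinNorms(), tmp)
  expect_identical(normEntries(readNorms(tmp)), normEntries(builtinNorms()))
})

test_that("normative z-scores match the case example at one decimal", {
  expect_equal(round(normativeZ(fisherZ(0.62), "anterior", stratum = "all"), 1),
               0.7)
  expect_equal(round(normativeZ(fisherZ(0.20), "posterior_to_anterior",
                                stratum = "all"), 1), -1.9)
  expect_equal(round(normativeZ(fisherZ(0.37), "whole_dmn", stratum = "all"),
                     1), 0)
  expect_equal(normativeZ(0.63, "anterior", stratum = "all"), 0)
  expect_error(normativeZ(0.5, "salience", stratum = "all"),
               "no normative entry")
})

test_that("age selects the stratum with an inclusive boundary at 50", {
  expect_equal(normativeZ(0.40, "whole_dmn", age = 50), 0)   # age_le_50
  expect_equal(normativeZ(0.36, "whole_dmn", age = 51), 0)   # age_gt_50
  expect_equal(normativeZ(0.39, "whole_dmn"), 0)             # no age: all
})

test_that("z-scoring is affine-equivariant in value and norm mean", {
  norms <- builtinNorms()
  shifted <- normEntries(norms)
  shifted$mean <- shifted$mean + 0.2
  shifted$p25 <- shifted$p25 + 0.2
  shifted$p75 <- shifted$p75 + 0.2
  nt <- new("NormTable", entries = shifted)
  expect_equal(normativeZ(0.5 + 0.2, "whole_dmn", stratum = "all", norms = nt),
               normativeZ(0.5, "whole_dmn", stratum = "all"))
})

test_that("the case example scores normal / normal / hypo-connected", {
  rep1 <- personReport(c(whole_dmn = 0.37, anterior = 0.62,
                         posterior_to_anterior = 0.20),
                       age = 39, pearson = TRUE, stratum = "all")
  t <- rep1@table
  expect_equal(round(t$fisherZ, 2), c(0.39, 0.73, 0.20))
  expect_equal(round(t$z, 1), c(0.0, 0.7, -1.9))
  expect_equal(t$severity, c("normal", "normal", "borderline"))
  expect_equal(t$direction, c("none", "none", "hypo"))
  expect_match(t$band[3], "hypo-connectivity")
  txt <- paste(capture.output(show(rep1)), collapse = "\n")
  expect_match(txt, "equal to the normative mean")
  expect_match(txt, "0.7 SD above the normative mean")
  expect_match(txt, "1.9 SD below the normative mean")
  expect_match(txt, "provisional")
})

test_that("values at the stratum means score exactly zero", {
  rep0 <- personReport(c(whole_dmn = 0.39, anterior = 0.63,
                         posterior_to_anterior = 0.47), stratum = "all")
  expect_equal(rep0@table$z, c(0, 0, 0))
  expect_true(all(rep0@table$severity == "normal"))
})

test_that("subjects drawn from the normative distribution rarely leave |z| < 3", {
  set.seed(51)
  e <- normEntries(builtinNorms())
  row <- e[e$network == "whole_dmn" & e$stratum == "all", ]
  draws <- rnorm(1000, row$mean, row$sd)
  z <- vapply(draws, normativeZ, numeric(1), network = "whole_dmn",
              stratum = "all")
  expect_gte(mean(abs(z) < 3), 0.99)
})

test_that("a report is produced end-to-end from a time series", {
  sim <- simulateSubject(simSpec(seed = 52))
  rep1 <- personReport(sim$series, age = 39,
                       subnetworks = sim$subnetworks)
  expect_s4_class(rep1, "PersonReport")
  expect_equal(rep1@stratum, "age_le_50")
  expect_setequal(rep1@table$network,
                  c("whole_dmn", "anterior", "posterior_to_anterior"))
  # the simulated subject sits near the norms, so everything is in band
  expect_true(all(abs(rep1@table$z) < 3))
  # insufficient data refuses to score
  short <- ParcelTimeSeries(matrix(rnorm(100 * 41), 100, 41,
                                   dimnames = list(NULL, regionIds(sim$series))),
                            tr = 2.5)
  expect_error(personReport(short, age = 39, subnetworks = sim$subnetworks),
               "insufficient data")
})
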