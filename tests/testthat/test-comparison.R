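# Condition summaries, fold changes, paired t-tests and intensity
# distributions.

test_that("condition medians match a sort-based oracle", {
  rec <- data.frame(trajectory_id = c("a", "b", "c"),
                    D_eff_um2_per_s = c(1, 2, 3), alpha = c(0.7, 0.9, 0.8))
  s <- summarizeCondition(rec, "ctrl", "r1")
  expect_equal(s@medianDeff, 2)
  expect_equal(s@medianAlpha, 0.8)
  one <- summarizeCondition(rec[2, ], "ctrl", "r1")
  expect_equal(one@medianDeff, 2)
  # larger set against an explicit sort-based median
  set.seed(9)
  v <- rlnorm(1001, -4, 0.6)
  big <- data.frame(trajectory_id = as.character(seq_along(v)),
                    D_eff_um2_per_s = v)
  sorted <- sort(v)
  expect_equal(summarizeCondition(big, "c", "r")@medianDeff, sorted[501])
  expect_error(summarizeCondition(big[0, ], "c", "r"), "empty")
})

test_that("fold change identities hold exactly", {
  rec <- data.frame(trajectory_id = letters[1:5],
                    D_eff_um2_per_s = c(.01, .02, .03, .04, .05))
  s <- summarizeCondition(rec, "x", "r1")
  expect_identical(foldChange(s, s), 1)
  rec2 <- rec; rec2$D_eff_um2_per_s <- rec$D_eff_um2_per_s * 2
  s2 <- summarizeCondition(rec2, "y", "r1")
  expect_equal(foldChange(s2, s), 2)
  expect_equal(foldChange(s2, s), 1 / foldChange(s, s2))
  zero <- summarizeCondition(
    data.frame(trajectory_id = "a", D_eff_um2_per_s = 0), "z", "r1")
  expect_error(foldChange(s, zero), "positive")
})

test_that("coordinate scaling by sqrt(2) doubles the recovered fold change", {
  ts <- simulateCondition(SimulationConfig(nTrajectories = 60, nFrames = 60,
                                           D = 0.01, seed = 27))
  recA <- analyzeTrajectories(ts)
  d <- trajectoryData(ts)
  d$x_um <- d$x_um * sqrt(2); d$y_um <- d$y_um * sqrt(2)
  recB <- analyzeTrajectories(TrajectorySet(d, frameInterval = 0.5))
  sA <- summarizeCondition(recA, "ref", "r1")
  sB <- summarizeCondition(recB, "test", "r1")
  expect_equal(foldChange(sB, sA), 2, tolerance = 1e-10)
})

test_that("simulated conditions recover their true D ratio", {
  mk <- function(D, seed) {
    ts <- simulateCondition(SimulationConfig(
      nTrajectories = 300, nFrames = 120, D = D, alpha = 1,
      locError = 0.02, seed = seed))
    summarizeCondition(analyzeTrajectories(ts), "c", "r")
  }
  ref <- mk(0.010, 31); tst <- mk(0.017, 32)
  expect_equal(foldChange(tst, ref), 1.7, tolerance = 0.10)
})

test_that("degenerate paired differences are flagged, not silently tested", {
  r1 <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_true(r1@degenerate)
  expect_true(is.na(r1@pValue))
  # constant nonzero shift: differences all -1, sd 0 -> degenerate too
  r2 <- pairedTTest(c(1, 2, 3), c(2, 3, 4))
  expect_true(r2@degenerate)
  expect_error(pairedTTest(1, c(1, 2)), "equal length")
  expect_error(pairedTTest(1, 2), "at least 2")
})

test_that("paired t-test is symmetric up to the sign of t", {
  a <- c(1.2, 1.5, 1.1); b <- c(1.0, 1.3, 1.2)
  ab <- pairedTTest(a, b); ba <- pairedTTest(b, a)
  expect_equal(ab@tStatistic, -ba@tStatistic)
  expect_equal(ab@pValue, ba@pValue)
  # agrees with the closed-form paired t on the differences
  dd <- a - b
  tManual <- mean(dd) / (sd(dd) / sqrt(3))
  expect_equal(ab@tStatistic, tManual)
  expect_equal(ab@pValue, 2 * pt(-abs(tManual), df = 2))
})

test_that("replicate-paired comparison uses matching labels", {
  mkSum <- function(D, cond, repl)
    summarizeCondition(data.frame(trajectory_id = letters[1:3],
                                  D_eff_um2_per_s = D * c(0.9, 1, 1.1)),
                       cond, repl)
  tst <- list(mkSum(2, "t", "r1"), mkSum(2.2, "t", "r2"),
              mkSum(1.8, "t", "r3"))
  ref <- list(mkSum(1, "c", "r2"), mkSum(1, "c", "r1"),
              mkSum(1, "c", "r3"))
  cmp <- compareConditions(tst, ref)
  expect_equal(cmp@foldChanges, c(2, 2.2, 1.8))
  expect_equal(cmp@meanFold, 2)
  badRef <- list(mkSum(1, "c", "rX"), mkSum(1, "c", "r1"),
                 mkSum(1, "c", "r3"))
  expect_error(compareConditions(tst, badRef), "replicate")
})

test_that("intensity distributions normalize and match sort oracles", {
  # constant vector: one occupied bin, zero IQR
  cst <- intensityDistribution(rep(5, 40), bins = 10)
  expect_equal(sum(cst$prob), 1)
  expect_equal(sum(cst$prob > 0), 1L)
  expect_equal(cst$iqr, 0)
  # linearity: doubling intensities doubles median and IQR
  set.seed(41)
  v <- rlnorm(500, 5, 0.5)
  d1 <- intensityDistribution(v); d2 <- intensityDistribution(2 * v)
  expect_equal(d2$median, 2 * d1$median)
  expect_equal(d2$iqr, 2 * d1$iqr)
  # histogram mass sums to 1; quantiles match explicit sort
  expect_equal(sum(d1$prob), 1)
  expect_equal(d1$median, sort(v)[c(250, 251)] |> mean())
  expect_error(intensityDistribution(numeric(0)), "empty")
  # rank-sum helper separates shifted distributions
  rs <- compareIntensities(v, v * 3)
  expect_lt(rs$p_value, 1e-6)
})
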