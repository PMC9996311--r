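# MSD estimators and short-time fits: hand-computed and brute-force
# oracles, closed-form projection identity, and geometric invariances.

test_that("TA-MSD matches the hand-computed overlapping-pair average", {
  tr <- data.frame(frame = 0:3, x_um = c(0, 1, 2, 3), y_um = 0)
  cv <- computeTAMSD(tr, frameInterval = 1)
  expect_equal(msd(cv), c(1, 4, 9))
  expect_equal(tau(cv), c(1, 2, 3))
  expect_equal(nPairs(cv), c(3L, 2L, 1L))
})

test_that("a stationary particle has identically zero MSD", {
  tr <- data.frame(frame = 0:20, x_um = 2.5, y_um = -1)
  expect_equal(msd(computeTAMSD(tr)), rep(0, 20))
})

test_that("TA-MSD equals a brute-force all-pairs implementation", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(12:60, 1)
    tr <- randomTrajectory(n)
    ml <- min(10, n - 1)
    cv <- computeTAMSD(tr, maxLag = ml, frameInterval = 0.5)
    expect_equal(msd(cv), bruteTAMSD(tr$x_um, tr$y_um, ml))
  }
})

test_that("frame gaps are rejected", {
  tr <- data.frame(frame = c(0, 1, 3, 4), x_um = 1:4, y_um = 0)
  expect_error(computeTAMSD(tr), "gap")
})

test_that("ensemble MSD is the unweighted mean over contributing tracks", {
  # two constant-velocity tracks with TA-MSD(tau1) = 2 and 4 um^2
  d <- rbind(
    data.frame(trajectory_id = "a", frame = 0:11,
               x_um = sqrt(2) * (0:11), y_um = 0),
    data.frame(trajectory_id = "b", frame = 0:11,
               x_um = 2 * (0:11), y_um = 0))
  ts <- TrajectorySet(d, frameInterval = 1)
  ens <- computeEnsembleMSD(ts, maxLag = 1)
  expect_equal(msd(ens), 3)
  expect_equal(nPairs(ens), 2L)
  # single trajectory: ensemble curve identical to its TA-MSD
  one <- TrajectorySet(d[d$trajectory_id == "a", ], frameInterval = 1)
  expect_equal(msd(computeEnsembleMSD(one, maxLag = 5)),
               msd(computeTAMSD(d[d$trajectory_id == "a", ], maxLag = 5,
                                frameInterval = 1)))
})

test_that("mixed-length ensembles match a brute-force re-average", {
  set.seed(5)
  lens <- sample(15:40, 12, replace = TRUE)
  d <- do.call(rbind, lapply(seq_along(lens), function(i) {
    tr <- randomTrajectory(lens[i])
    tr$trajectory_id <- sprintf("t%02d", i)
    tr
  }))
  ts <- TrajectorySet(d, frameInterval = 0.5)
  maxLag <- 30
  ens <- computeEnsembleMSD(ts, maxLag = maxLag)
  # oracle: accumulate per-trajectory brute-force curves lag by lag
  acc <- numeric(maxLag); cnt <- integer(maxLag)
  for (i in seq_along(lens)) {
    tr <- d[d$trajectory_id == sprintf("t%02d", i), ]
    bm <- bruteTAMSD(tr$x_um, tr$y_um, min(maxLag, nrow(tr) - 1))
    k <- seq_along(bm)
    acc[k] <- acc[k] + bm; cnt[k] <- cnt[k] + 1L
  }
  expect_equal(msd(ens), (acc / cnt)[cnt > 0])
  expect_equal(nPairs(ens), cnt[cnt > 0])
  expect_true(all(diff(nPairs(ens)) <= 0))
})

test_that("length filter keeps exactly the tracks above the threshold", {
  ts <- makeLengthSet(5:15)
  kept <- filterTrajectories(ts, minPoints = 11, quiet = TRUE)
  expect_equal(unname(sort(trajectoryLengths(kept))), 11:15)
  counts <- attr(kept, "filterCounts")
  expect_equal(unname(counts["kept"]), 5L)
  expect_equal(unname(counts["dropped"]), 6L)
  # empty in, empty out
  empty <- simulateCondition(SimulationConfig(nTrajectories = 0, seed = 1))
  expect_equal(nTrajectories(filterTrajectories(empty, quiet = TRUE)), 0L)
  # uniformly long ensemble is untouched
  long <- simulateCondition(SimulationConfig(nTrajectories = 20,
                                             nFrames = 240, seed = 4))
  expect_equal(nTrajectories(filterTrajectories(long, quiet = TRUE)), 20L)
})

test_that("through-origin D fit is exact on model curves", {
  tt <- (1:10) * 0.5
  expect_equal(Deff(fitDeff(MSDCurve(tt, 4 * tt, rep(50, 10)))), 1)
  expect_equal(Deff(fitDeff(MSDCurve(tt, 2 * tt, rep(50, 10)))), 0.5)
  # all-zero MSD -> D = 0
  z <- MSDCurve(tt, rep(0, 10), rep(50, 10))
  expect_equal(Deff(fitDeff(z)), 0)
  expect_error(fitDeff(MSDCurve(tt[1:5], 4 * tt[1:5], rep(9, 5))), "lags")
})

test_that("fitDeff equals the closed-form projection sum(tau*msd)/(4*sum(tau^2))", {
  set.seed(8)
  for (i in 1:20) {
    tt <- (1:10) * 0.5
    mm <- abs(rnorm(10, mean = 4 * tt * 0.02, sd = 0.01))
    cv <- MSDCurve(tt, mm, rep(30, 10))
    expect_equal(Deff(fitDeff(cv)), sum(tt * mm) / (4 * sum(tt^2)),
                 tolerance = 1e-12)
  }
})

test_that("fitDeff agrees with an independent grid-search oracle", {
  ts <- simulateCondition(SimulationConfig(
    nTrajectories = 100, nFrames = 60, D = 0.01, alpha = 0.8,
    locError = 0.02, seed = 21))
  rec <- analyzeTrajectories(ts)
  curves <- computeTAMSD(filterTrajectories(ts, quiet = TRUE), maxLag = 10)
  oracle <- vapply(curves, function(cv)
    gridSearchDeff(tau(cv), msd(cv)), numeric(1))
  expect_equal(median(rec$D_eff_um2_per_s), median(oracle),
               tolerance = 0.15)
})

test_that("log-log alpha fit recovers exact power laws", {
  tt <- (1:10) * 0.5
  f1 <- fitAlpha(MSDCurve(tt, 4 * tt, rep(50, 10)))
  expect_equal(alphaExponent(f1), 1)
  expect_equal(Deff(f1), 1)
  f2 <- fitAlpha(MSDCurve(tt, tt^0.5, rep(50, 10)))
  expect_equal(alphaExponent(f2), 0.5)
  expect_error(fitAlpha(MSDCurve(tt, c(0, tt[-1]), rep(50, 10))),
               "non-positive")
})

test_that("MSD and fits are invariant under rigid motions and scale as c^2", {
  set.seed(31)
  tr <- randomTrajectory(40)
  cv <- computeTAMSD(tr, maxLag = 10, frameInterval = 0.5)
  # translation
  tr2 <- transform(tr, x_um = x_um + 5, y_um = y_um - 3)
  expect_equal(msd(computeTAMSD(tr2, maxLag = 10, frameInterval = 0.5)),
               msd(cv))
  # rotation by 37 degrees
  th <- 37 * pi / 180
  tr3 <- data.frame(frame = tr$frame,
                    x_um = cos(th) * tr$x_um - sin(th) * tr$y_um,
                    y_um = sin(th) * tr$x_um + cos(th) * tr$y_um)
  expect_equal(msd(computeTAMSD(tr3, maxLag = 10, frameInterval = 0.5)),
               msd(cv))
  # scaling by c multiplies MSD and D_eff by c^2, leaves alpha unchanged
  cc <- 1.7
  tr4 <- transform(tr, x_um = cc * x_um, y_um = cc * y_um)
  cv4 <- computeTAMSD(tr4, maxLag = 10, frameInterval = 0.5)
  expect_equal(msd(cv4), cc^2 * msd(cv))
  expect_equal(Deff(fitDeff(cv4)), cc^2 * Deff(fitDeff(cv)))
  expect_equal(alphaExponent(fitAlpha(cv4)), alphaExponent(fitAlpha(cv)),
               tolerance = 1e-10)
})

test_that("per-trajectory analysis excludes zero-MSD tracks from alpha only", {
  d <- rbind(
    data.frame(trajectory_id = "moving", frame = 0:11,
               x_um = (0:11) * 0.1, y_um = 0),
    data.frame(trajectory_id = "frozen", frame = 0:11, x_um = 1, y_um = 1))
  ts <- TrajectorySet(d, frameInterval = 0.5)
  rec <- analyzeTrajectories(ts)
  frozen <- rec[rec$trajectory_id == "frozen", ]
  expect_equal(frozen$D_eff_um2_per_s, 0)
  expect_true(is.na(frozen$alpha))
  expect_equal(attr(rec, "alphaExcluded"), 1L)
})
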