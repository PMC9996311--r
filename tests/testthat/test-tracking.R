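# Spot detection, linking and intensity measurement.

test_that("blank and constant frames yield no detections", {
  p <- TrackingParams(percentile = 1)
  expect_equal(nrow(detectSpots(matrix(0, 32, 32), p)), 0L)
  expect_equal(nrow(detectSpots(matrix(7, 32, 32), p)), 0L)
  expect_error(detectSpots(array(0, c(4, 4, 4)), p), "matrix")
  expect_error(detectSpots(matrix(0, 3, 3), p), "smaller")
})

test_that("a noiseless Gaussian spot is localized to within 0.1 px", {
  img <- gaussianSpotImage(64, 64, x0 = 17.30, y0 = 41.70, sigma = 1.2)
  d <- detectSpots(img, TrackingParams(percentile = 1))
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x_px - 17.30), 0.1)
  expect_lt(abs(d$y_px - 41.70), 0.1)
  expect_gt(d$mass, 0)
})

test_that("well-separated spots are detected individually", {
  img <- gaussianSpotImage(64, 64, 15, 15) +
    gaussianSpotImage(64, 64, 35, 15) # 20 px apart
  d <- detectSpots(img, TrackingParams(percentile = 1))
  expect_equal(nrow(d), 2L)
})

test_that("integer translation of the image translates all detections", {
  set.seed(10)
  base <- gaussianSpotImage(96, 96, 20.4, 30.8) +
    gaussianSpotImage(96, 96, 60.1, 70.6, amp = 700)
  shifted <- matrix(0, 96, 96)
  shifted[(1 + 5):96, (1 + 9):96] <- base[1:(96 - 5), 1:(96 - 9)]
  p <- TrackingParams(percentile = 1)
  d0 <- detectSpots(base, p)
  d1 <- detectSpots(shifted, p)
  d1 <- d1[d1$x_px > 9 + 4 & d1$y_px > 5 + 4, ]   # ignore the wrapped-in edge
  expect_equal(nrow(d1), nrow(d0))
  expect_equal(sort(d1$x_px), sort(d0$x_px) + 9, tolerance = 1e-6)
  expect_equal(sort(d1$y_px), sort(d0$y_px) + 5, tolerance = 1e-6)
})

test_that("a single drifting detection links into one trajectory", {
  det <- data.frame(frame = 0:9, x_px = (0:9) * 3, y_px = 10,
                    mass = 1, mean_intensity = 5)
  ts <- linkSpots(det, TrackingParams(percentile = 1, maxDisp = 5))
  expect_equal(nTrajectories(ts), 1L)
  expect_equal(unname(trajectoryLengths(ts)), 10L)
  # and positions come out in micrometres
  expect_equal(sort(trajectoryData(ts)$x_um), (0:9) * 3 * 0.18)
})

test_that("distant particles never swap identity", {
  det <- rbind(
    data.frame(frame = rep(0:9, each = 1), x_px = 5 + (0:9) * 0.5,
               y_px = 5, mass = 1, mean_intensity = 1),
    data.frame(frame = 0:9, x_px = 50 - (0:9) * 0.5, y_px = 50,
               mass = 1, mean_intensity = 1))
  ts <- linkSpots(det, TrackingParams(maxDisp = 5))
  expect_equal(nTrajectories(ts), 2L)
  d <- trajectoryData(ts)
  # each trajectory stays on its own side of the field
  sides <- tapply(d$y_um, d$trajectory_id, function(v) length(unique(v)))
  expect_true(all(sides == 1))
})

test_that("linking is invariant to detection row order", {
  set.seed(12)
  det <- do.call(rbind, lapply(0:5, function(f)
    data.frame(frame = f,
               x_px = c(10, 30, 50) + rnorm(3, sd = 0.5),
               y_px = c(10, 30, 50), mass = 1, mean_intensity = 1)))
  p <- TrackingParams(maxDisp = 5)
  a <- linkSpots(det, p)
  b <- linkSpots(det[sample(nrow(det)), ], p)
  expect_identical(trajectoryData(a), trajectoryData(b))
})

test_that("no detection is used twice and no frame repeats in a track", {
  set.seed(14)
  det <- do.call(rbind, lapply(0:19, function(f)
    data.frame(frame = f, x_px = runif(8, 0, 60), y_px = runif(8, 0, 60),
               mass = 1, mean_intensity = 1)))
  for (method in c("greedy", "hungarian")) {
    ts <- linkSpots(det, TrackingParams(maxDisp = 5, method = method))
    d <- trajectoryData(ts)
    expect_equal(nrow(d), nrow(det))   # every detection appears exactly once
    expect_equal(anyDuplicated(d[, c("trajectory_id", "frame")]), 0L)
  }
})

test_that("hungarian assignment minimizes total squared displacement", {
  # geometry where greedy takes the locally shortest link (1 -> 0.9, cost
  # 0.01) and is forced into 0 -> 2.0 (cost 4), total 4.01; the optimal
  # pairing is 0 -> 0.9 and 1 -> 2.0, total 1.81
  det <- rbind(
    data.frame(frame = 0, x_px = c(0, 1), y_px = 0,
               mass = 1, mean_intensity = 1),
    data.frame(frame = 1, x_px = c(0.9, 2.0), y_px = 0,
               mass = 1, mean_intensity = 1))
  tsH <- linkSpots(det, TrackingParams(maxDisp = 5, method = "hungarian"))
  idsH <- split(trajectoryData(tsH)$x_um / 0.18,
                trajectoryData(tsH)$trajectory_id)
  expect_true(any(vapply(idsH, function(v)
    isTRUE(all.equal(v, c(0, 0.9))), logical(1))))
  expect_true(any(vapply(idsH, function(v)
    isTRUE(all.equal(v, c(1, 2.0))), logical(1))))
  tsG <- linkSpots(det, TrackingParams(maxDisp = 5, method = "greedy"))
  idsG <- split(trajectoryData(tsG)$x_um / 0.18,
                trajectoryData(tsG)$trajectory_id)
  expect_true(any(vapply(idsG, function(v)
    isTRUE(all.equal(v, c(1, 0.9))), logical(1))))
})

test_that("hungarian and greedy agree with brute-force optimal cost", {
  # exhaustive assignment oracle on small random instances
  set.seed(15)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n, 0, 10), n)
    best <- min(vapply(perms(seq_len(n)), function(p)
      sum(cost[cbind(seq_len(n), p)]), numeric(1)))
    hmatch <- rheoSPT:::.hungarian(cost)
    expect_equal(sum(cost[cbind(seq_len(n), hmatch)]), best)
  }
})

test_that("disk-mean intensity has exact trivial and linear behaviour", {
  mv <- Movie(array(3.5, c(32, 32, 4)))
  tr <- data.frame(frame = 0:3, x_px = 15, y_px = 15)
  mi <- measureIntensity(mv, tr)
  expect_equal(mi$perFrame, rep(3.5, 4))
  expect_equal(mi$average, 3.5)
  expect_false(mi$edgeClipped)
  mv2 <- Movie(mv@frames * 2)
  expect_equal(measureIntensity(mv2, tr)$average, 7)
})

test_that("disk mean of a rendered Gaussian matches the analytic integral", {
  s <- 1.5; amp <- 900; r <- 3
  img <- gaussianSpotImage(41, 41, x0 = 20, y0 = 20, sigma = s, amp = amp)
  mv <- Movie(array(img, c(41, 41, 1)))
  mi <- measureIntensity(mv, data.frame(frame = 0, x_px = 20, y_px = 20),
                         radius = r)
  # analytic oracle: Gaussian integral over the disk,
  # amp * 2*pi*s^2 * (1 - exp(-r^2 / (2 s^2))), divided by the area of the
  # measured (pixelated) disk -- the number of in-disk pixel centres
  npix <- sum(outer(-r:r, -r:r, function(a, b) a^2 + b^2) <= r^2)
  oracle <- amp * 2 * pi * s^2 * (1 - exp(-r^2 / (2 * s^2))) / npix
  expect_equal(mi$average, oracle, tolerance = 0.02)
})

test_that("edge-clipped disks are flagged and use the in-field pixels", {
  mv <- Movie(array(2, c(20, 20, 1)))
  mi <- measureIntensity(mv, data.frame(frame = 0, x_px = 0, y_px = 0))
  expect_true(mi$edgeClipped)
  expect_equal(mi$average, 2)
  expect_error(
    measureIntensity(mv, data.frame(frame = 5, x_px = 1, y_px = 1)),
    "range")
})
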