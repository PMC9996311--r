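# Independent oracles and fixture builders used across tests. These stay
# deliberately naive (double loops, grid searches) so they cannot share a
# defect with the vectorized implementations they check.

# Brute-force TA-MSD: explicit double loop over all overlapping pairs
bruteTAMSD <- function(x, y, maxLag) {
  n <- length(x)
  vapply(seq_len(maxLag), function(k) {
    acc <- 0
    for (i in 1:(n - k))
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    acc / (n - k)
  }, numeric(1))
}

# Grid-search least squares for MSD = 4*D*tau (through the origin)
gridSearchDeff <- function(tauv, msdv, lo = 1e-5, hi = 1, nGrid = 20000) {
  Ds <- exp(seq(log(lo), log(hi), length.out = nGrid))
  sse <- vapply(Ds, function(D) sum((msdv - 4 * D * tauv)^2), numeric(1))
  Ds[which.min(sse)]
}

# Render a single noiseless Gaussian spot into a matrix ([row = y, col = x],
# 0-based pixel-centre coordinates)
gaussianSpotImage <- function(nrow, ncol, x0, y0, sigma = 1.2, amp = 1000,
                              background = 0) {
  gx <- exp(-((0:(ncol - 1)) - x0)^2 / (2 * sigma^2))
  gy <- exp(-((0:(nrow - 1)) - y0)^2 / (2 * sigma^2))
  background + amp * outer(gy, gx)
}

# TrajectorySet with prescribed per-trajectory lengths, one stationary
# particle per trajectory
makeLengthSet <- function(lengths, frameInterval = 0.5) {
  d <- do.call(rbind, lapply(seq_along(lengths), function(i) {
    data.frame(trajectory_id = sprintf("t%02d", i),
               frame = 0:(lengths[i] - 1),
               x_um = i, y_um = i)
  }))
  TrajectorySet(d, frameInterval = frameInterval)
}

# Random-walk trajectory table for oracle checks
randomTrajectory <- function(n, dt = 0.5, sd = 0.1) {
  data.frame(frame = 0:(n - 1),
             x_um = cumsum(c(0, rnorm(n - 1, sd = sd))),
             y_um = cumsum(c(0, rnorm(n - 1, sd = sd))))
}
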