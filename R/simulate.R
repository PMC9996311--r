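## Trajectory simulation: 2D fractional Brownian motion with static
## localization noise. Each coordinate is an independent fBm with Hurst
## exponent H = alpha/2 scaled so Var[x(t)] = 2*D*t^alpha, giving the 2D
## power-law MSD 4*D*tau^alpha.

# Autocovariance of fractional Gaussian noise (unit-variance increments),
# gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2
.fgnAutocov <- function(k, H) {
  (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H)) / 2
}

# Circulant-embedding eigenvalues for fGn of length m and Hurst H.
# Returns NULL when the embedding is not non-negative definite (then the
# caller falls back to Cholesky). Memoized per (m, H): ensembles share one
# eigenvalue computation.
.fgnCache <- new.env(parent = emptyenv())

.fgnCircEigen <- function(m, H) {
  key <- sprintf("%d_%.12g", m, H)
  if (!is.null(.fgnCache[[key]])) {
    ev <- .fgnCache[[key]]
    return(if (identical(ev, FALSE)) NULL else ev)
  }
  g <- .fgnAutocov(0:(m - 1), H)
  row <- c(g, .fgnAutocov(m, H), rev(g[-1]))   # length 2m
  ev <- Re(stats::fft(row))
  if (any(ev < -1e-8 * max(abs(ev)))) {
    .fgnCache[[key]] <- FALSE
    return(NULL)
  }
  ev <- pmax(ev, 0)
  .fgnCache[[key]] <- ev
  ev
}

# One fGn sample of length m given precomputed circulant eigenvalues
# (Davies-Harte). Consumes 2m standard normals.
.fgnSampleCirc <- function(m, ev) {
  M <- 2L * m
  z1 <- stats::rnorm(M)
  # V_0 and V_m are real; interior frequencies are complex conjugate pairs
  v <- complex(length.out = M)
  v[1] <- sqrt(ev[1]) * z1[1]
  v[m + 1] <- sqrt(ev[m + 1]) * z1[2]
  a <- z1[3:(m + 1)]
  b <- z1[(m + 2):M]
  k <- 2:m
  v[k] <- sqrt(ev[k] / 2) * complex(real = a, imaginary = b)
  v[M:(m + 2)] <- Conj(v[k])
  Re(stats::fft(v))[seq_len(m)] / sqrt(M)
}

# Cholesky fallback for short paths / indefinite embeddings
.fgnSampleChol <- function(m, H) {
  cov <- stats::toeplitz(.fgnAutocov(0:(m - 1), H))
  L <- chol(cov)
  as.numeric(crossprod(L, stats::rnorm(m)))
}

# Draw n fGn vectors of length m with Hurst H; returns an m x n matrix.
# Uses circulant embedding where the embedding is valid, else Cholesky.
.fgnDraw <- function(m, H, n) {
  if (abs(H - 0.5) < 1e-12)  # Brownian limit: i.i.d. increments
    return(matrix(stats::rnorm(m * n), nrow = m))
  ev <- if (m >= 8) .fgnCircEigen(m, H) else NULL
  if (is.null(ev)) {
    matrix(replicate(n, .fgnSampleChol(m, H)), nrow = m)
  } else {
    matrix(replicate(n, .fgnSampleCirc(m, ev)), nrow = m)
  }
}

#' Simulate a single 2D fBm trajectory
#'
#' Generates one trajectory of \code{nFrames} localizations. Each coordinate
#' follows an independent fractional Brownian motion with
#' \code{Var[x(t)] = 2 * D * t^alpha} (Hurst exponent \code{alpha/2}), so the
#' noise-free 2D MSD is \code{4 * D * tau^alpha}. Independent Gaussian
#' localization noise of standard deviation \code{locError} is added to every
#' coordinate, which raises the observed MSD by a constant offset of
#' approximately \code{4 * locError^2}. The start position is drawn uniformly
#' over the field of view. Uses the current RNG state; call
#' \code{set.seed} or \code{\link{simulateCondition}} for reproducibility.
#'
#' @param cfg a \code{\linkS4class{SimulationConfig}} (its \code{seed} slot is
#'   ignored here; seeding is the caller's responsibility).
#' @return data.frame with columns \code{frame} (0-based), \code{x_um},
#'   \code{y_um}.
#' @examples
#' set.seed(1)
#' tr <- simulateTrajectory(SimulationConfig(nFrames = 100, D = 0.01,
#'                                           alpha = 0.8))
#' head(tr)
#' @export
simulateTrajectory <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  n <- cfg@nFrames
  m <- n - 1L
  fieldUm <- cfg@fov * cfg@pixelSize
  start <- stats::runif(2, 0, fieldUm)
  if (cfg@D == 0) {
    x <- rep(start[1], n)
    y <- rep(start[2], n)
  } else {
    sigma <- sqrt(2 * cfg@D * cfg@frameInterval^cfg@alpha)
    inc <- sigma * .fgnDraw(m, cfg@alpha / 2, 2L)
    x <- start[1] + c(0, cumsum(inc[, 1]))
    y <- start[2] + c(0, cumsum(inc[, 2]))
  }
  if (cfg@locError > 0) {
    x <- x + stats::rnorm(n, sd = cfg@locError)
    y <- y + stats::rnorm(n, sd = cfg@locError)
  }
  data.frame(frame = 0:(n - 1L), x_um = x, y_um = y)
}

#' Simulate an ensemble of trajectories for one condition
#'
#' Draws \code{nTrajectories} independent trajectories from
#' \code{\link{simulateTrajectory}} under a single seeded RNG stream
#' (\code{cfg@seed}), so identical configurations reproduce bitwise-identical
#' tables. Trajectory ids are \code{"traj_0001"}, \code{"traj_0002"}, ...
#'
#' For efficiency the fGn circulant eigenvalues are computed once and shared
#' across trajectories.
#'
#' @param cfg a \code{\linkS4class{SimulationConfig}}.
#' @return a \code{\linkS4class{TrajectorySet}}; the \code{intensity} column
#'   is \code{NA} (intensities exist only after rendering and tracking).
#' @examples
#' ts <- simulateCondition(SimulationConfig(nTrajectories = 5, nFrames = 20,
#'                                          seed = 42))
#' ts
#' @export
simulateCondition <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  nT <- cfg@nTrajectories
  if (nT == 0L) {
    return(TrajectorySet(
      data.frame(trajectory_id = character(0), frame = integer(0),
                 x_um = numeric(0), y_um = numeric(0)),
      pixelSize = cfg@pixelSize, frameInterval = cfg@frameInterval))
  }
  out <- vector("list", nT)
  for (i in seq_len(nT)) {
    tr <- simulateTrajectory(cfg)
    tr$trajectory_id <- sprintf("traj_%04d", i)
    out[[i]] <- tr
  }
  d <- do.call(rbind, out)
  TrajectorySet(d[, c("trajectory_id", "frame", "x_um", "y_um")],
                pixelSize = cfg@pixelSize, frameInterval = cfg@frameInterval)
}
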