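#' Construct a TrajectorySet
#'
#' @param data data.frame with columns \code{trajectory_id}, \code{frame},
#'   \code{x_um}, \code{y_um} and optionally \code{intensity}.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame.
#' @return a \code{\linkS4class{TrajectorySet}}.
#' @examples
#' d <- data.frame(trajectory_id = "t1", frame = 0:3,
#'                 x_um = c(0, 1, 2, 3), y_um = 0)
#' ts <- TrajectorySet(d, pixelSize = 0.18, frameInterval = 0.5)
#' nTrajectories(ts)
#' @export
TrajectorySet <- function(data, pixelSize = 0.18, frameInterval = 0.5) {
  if (!"intensity" %in% names(data))
    data$intensity <- rep(NA_real_, nrow(data))
  data <- data[, .TRAJ_COLS]
  data$trajectory_id <- as.character(data$trajectory_id)
  data$frame <- as.integer(data$frame)
  # time-order within trajectory; stable across input row order
  data <- data[order(data$trajectory_id, data$frame), , drop = FALSE]
  rownames(data) <- NULL
  new("TrajectorySet", data = data,
      pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval))
}

#' Accessors for TrajectorySet
#'
#' \code{trajectoryData} returns the localization table; \code{pixelSize} and
#' \code{frameInterval} the acquisition metadata; \code{nTrajectories} the
#' number of distinct trajectories; \code{trajectoryLengths} a named vector
#' of localization counts per trajectory.
#'
#' @param x a \code{TrajectorySet}.
#' @name TrajectorySet-accessors
NULL

#' @rdname TrajectorySet-accessors
#' @export
setMethod("trajectoryData", "TrajectorySet", function(x) x@data)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("pixelSize", "TrajectorySet", function(x) x@pixelSize)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("pixelSize", "Movie", function(x) x@pixelSize)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("frameInterval", "TrajectorySet", function(x) x@frameInterval)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("frameInterval", "Movie", function(x) x@frameInterval)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("nTrajectories", "TrajectorySet",
          function(x) length(unique(x@data$trajectory_id)))

#' @rdname TrajectorySet-accessors
#' @export
setMethod("trajectoryLengths", "TrajectorySet", function(x) {
  if (nrow(x@data) == 0) return(integer(0))
  tab <- table(x@data$trajectory_id)
  stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "TrajectorySet", function(object) {
  n <- nTrajectories(object)
  len <- trajectoryLengths(object)
  cat("TrajectorySet with", n, "trajectories,",
      nrow(object@data), "localizations\n")
  if (n > 0)
    cat("  lengths:", min(len), "-", max(len), "points\n")
  cat("  pixelSize:", object@pixelSize, "um; frameInterval:",
      object@frameInterval, "s\n")
})

#' Split a TrajectorySet into per-trajectory data.frames
#'
#' @param x a \code{TrajectorySet}.
#' @return named list of single-trajectory data.frames, time-ordered.
#' @export
splitTrajectories <- function(x) {
  stopifnot(is(x, "TrajectorySet"))
  split(x@data, x@data$trajectory_id)
}

#' Construct an MSDCurve
#'
#' @param tau time delays in seconds.
#' @param msd MSD values in um^2.
#' @param nPairs displacement-pair (or contributing-trajectory) counts.
#' @param kind \code{"time_averaged"} or \code{"ensemble"}.
#' @return an \code{\linkS4class{MSDCurve}}.
#' @export
MSDCurve <- function(tau, msd, nPairs, kind = "time_averaged") {
  new("MSDCurve", tau = as.numeric(tau), msd = as.numeric(msd),
      nPairs = as.integer(nPairs), kind = kind)
}

#' Accessors for MSDCurve
#'
#' @param x an \code{MSDCurve}.
#' @name MSDCurve-accessors
NULL

#' @rdname MSDCurve-accessors
#' @export
setMethod("tau", "MSDCurve", function(x) x@tau)

#' @rdname MSDCurve-accessors
#' @export
setMethod("msd", "MSDCurve", function(x) x@msd)

#' @rdname MSDCurve-accessors
#' @export
setMethod("nPairs", "MSDCurve", function(x) x@nPairs)

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve (%s), %d lags, tau %.3g - %.3g s\n",
              object@kind, length(object@tau),
              if (length(object@tau)) object@tau[1] else NA,
              if (length(object@tau)) object@tau[length(object@tau)] else NA))
})

#' Plot an MSD curve on log-log axes
#'
#' @param x an \code{MSDCurve}.
#' @param y ignored.
#' @param ... passed to \code{plot}.
#' @export
setMethod("plot", signature(x = "MSDCurve", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@tau, x@msd, log = "xy",
                   xlab = expression(tau ~ "(s)"),
                   ylab = expression(MSD ~ (mu * m^2)), ...)
  })

#' Accessors for RheologyFit
#'
#' \code{Deff} returns the (effective or generalized) diffusion coefficient;
#' \code{alphaExponent} the anomalous exponent.
#'
#' @param x a \code{RheologyFit}.
#' @name RheologyFit-accessors
NULL

#' @rdname RheologyFit-accessors
#' @export
setMethod("Deff", "RheologyFit", function(x) x@Deff)

#' @rdname RheologyFit-accessors
#' @export
setMethod("alphaExponent", "RheologyFit", function(x) x@alpha)

setMethod("show", "RheologyFit", function(object) {
  cat(sprintf("RheologyFit (%s scope, %d lags): D = %.4g", object@scope,
              object@nLagsUsed, object@Deff))
  if (!is.na(object@alpha)) cat(sprintf(", alpha = %.3f", object@alpha))
  cat(sprintf(", R^2 = %.3f\n", object@rSquared))
})

#' Construct a SimulationConfig
#'
#' @param nTrajectories number of trajectories.
#' @param nFrames localizations per trajectory.
#' @param frameInterval frame interval, seconds.
#' @param pixelSize pixel size, micrometres.
#' @param D generalized diffusion coefficient, um^2/s^alpha.
#' @param alpha anomalous exponent in (0, 2).
#' @param locError localization noise SD per coordinate, um.
#' @param fov field-of-view width, pixels.
#' @param seed integer seed.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @examples
#' cfg <- SimulationConfig(nTrajectories = 10, nFrames = 50, D = 0.01,
#'                         alpha = 0.8, seed = 7)
#' @export
SimulationConfig <- function(nTrajectories = 100, nFrames = 240,
                             frameInterval = 0.5, pixelSize = 0.18,
                             D = 0.01, alpha = 1, locError = 0,
                             fov = 200, seed = 1) {
  new("SimulationConfig",
      nTrajectories = as.integer(nTrajectories),
      nFrames = as.integer(nFrames),
      frameInterval = as.numeric(frameInterval),
      pixelSize = as.numeric(pixelSize),
      D = as.numeric(D), alpha = as.numeric(alpha),
      locError = as.numeric(locError),
      fov = as.integer(fov), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d trajectories x %d frames, ",
                     "dt = %g s, D = %g um^2/s^alpha, alpha = %g, ",
                     "locError = %g um, seed = %d\n"),
              object@nTrajectories, object@nFrames, object@frameInterval,
              object@D, object@alpha, object@locError, object@seed))
})

#' Construct a RenderConfig
#'
#' @param psfSigma Gaussian PSF sigma, pixels.
#' @param peakIntensity median per-particle peak amplitude, counts.
#' @param peakSdLog log-sd of the per-particle peak distribution (0 = fixed).
#' @param background constant background, counts.
#' @param noiseModel "none", "poisson" or "gaussian".
#' @param noiseSd Gaussian noise SD, counts.
#' @param bitDepth 8 or 16.
#' @return a \code{\linkS4class{RenderConfig}}.
#' @export
RenderConfig <- function(psfSigma = 1.2, peakIntensity = 1000,
                         peakSdLog = 0, background = 100,
                         noiseModel = "none", noiseSd = 10, bitDepth = 16) {
  new("RenderConfig", psfSigma = as.numeric(psfSigma),
      peakIntensity = as.numeric(peakIntensity),
      peakSdLog = as.numeric(peakSdLog),
      background = as.numeric(background),
      noiseModel = noiseModel, noiseSd = as.numeric(noiseSd),
      bitDepth = as.integer(bitDepth))
}

#' Construct TrackingParams
#'
#' @param radius detection radius, pixels.
#' @param cutoff non-particle discrimination threshold (only 0 supported).
#' @param percentile percent of brightest pixels considered spot candidates.
#' @param linkRange link range in frames (only 1 supported).
#' @param maxDisp maximum frame-to-frame displacement, pixels.
#' @param method "greedy" or "hungarian" assignment.
#' @return a \code{\linkS4class{TrackingParams}}.
#' @export
TrackingParams <- function(radius = 2, cutoff = 0, percentile = 0.5,
                           linkRange = 1, maxDisp = 5, method = "greedy") {
  new("TrackingParams", radius = as.integer(radius),
      cutoff = as.numeric(cutoff), percentile = as.numeric(percentile),
      linkRange = as.integer(linkRange), maxDisp = as.numeric(maxDisp),
      method = method)
}

#' Construct a Movie
#'
#' @param frames numeric array \code{[row, col, frame]} or list of matrices.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame.
#' @return a \code{\linkS4class{Movie}}.
#' @export
Movie <- function(frames, pixelSize = 0.18, frameInterval = 0.5) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  new("Movie", frames = frames, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval))
}

setMethod("show", "Movie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Movie: %d frames of %d x %d px, %g um/px, %g s/frame\n",
              d[3], d[1], d[2], object@pixelSize, object@frameInterval))
})

#' Number of frames in a Movie
#' @param movie a \code{Movie}.
#' @export
nFrames <- function(movie) dim(movie@frames)[3]

#' Extract one frame of a Movie as a matrix
#' @param movie a \code{Movie}.
#' @param i frame index (1-based).
#' @export
getFrame <- function(movie, i) movie@frames[, , i]

setMethod("show", "ConditionSummary", function(object) {
  cat(sprintf(paste0("ConditionSummary '%s' (replicate %s): %d trajectories",
                     "\n  median D_eff = %.4g um^2/s, median alpha = %.3f\n"),
              object@condition, object@replicate, object@nTrajectories,
              object@medianDeff, object@medianAlpha))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult (%s): mean fold change %.3f +/- %.3f\n",
              object@test, object@meanFold, object@sdFold))
  if (object@degenerate) {
    cat("  paired differences have zero variance; t statistic undefined\n")
  } else {
    cat(sprintf("  paired medians: t = %.3f, p = %.4g\n",
                object@tStatistic, object@pValue))
    cat(sprintf("  fold changes vs 1: t = %.3f, p = %.4g\n",
                object@tStatisticFold, object@pValueFold))
  }
})
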