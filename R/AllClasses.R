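#' @import methods
NULL

# Shared column layout for trajectory tables; pixels are converted to
# micrometres as early as possible and analysis never sees pixel units.
.TRAJ_COLS <- c("trajectory_id", "frame", "x_um", "y_um", "intensity")

#' TrajectorySet: a table of particle trajectories with acquisition metadata
#'
#' Container for a set of single-particle trajectories. Each row is one
#' localization; trajectories are identified by \code{trajectory_id} and are
#' time-ordered by the 0-based \code{frame} column. Positions are stored in
#' micrometres; the per-localization \code{intensity} column is optional
#' (\code{NA} when not measured). Acquisition metadata (pixel size and frame
#' interval) travel with the object so downstream MSD analysis needs no
#' extra arguments.
#'
#' @slot data \code{data.frame} with columns \code{trajectory_id},
#'   \code{frame}, \code{x_um}, \code{y_um}, \code{intensity}.
#' @slot pixelSize pixel size in micrometres per pixel.
#' @slot frameInterval frame interval in seconds.
#'
#' @seealso \code{\link{simulateCondition}}, \code{\link{readTrajectories}},
#'   \code{\link{trackMovie}}
#' @export
setClass("TrajectorySet",
  representation(
    data = "data.frame",
    pixelSize = "numeric",
    frameInterval = "numeric"
  ),
  prototype(
    data = data.frame(
      trajectory_id = character(0), frame = integer(0),
      x_um = numeric(0), y_um = numeric(0), intensity = numeric(0)
    ),
    pixelSize = 0.18,
    frameInterval = 0.5
  )
)

setValidity("TrajectorySet", function(object) {
  msg <- character(0)
  d <- object@data
  if (!all(.TRAJ_COLS %in% names(d)))
    msg <- c(msg, paste0("data must have columns: ",
                         paste(.TRAJ_COLS, collapse = ", ")))
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number")
  if (all(.TRAJ_COLS %in% names(d)) && nrow(d) > 0) {
    if (anyNA(d$frame) || any(d$frame < 0) || any(d$frame != floor(d$frame)))
      msg <- c(msg, "frame must contain non-negative integers")
    key <- paste(d$trajectory_id, d$frame)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (trajectory_id, frame) pair present")
  }
  if (length(msg)) msg else TRUE
})

#' MSDCurve: mean-squared displacement versus time delay
#'
#' Holds an MSD curve on an evenly spaced lag grid. For a time-averaged curve
#' (\code{kind = "time_averaged"}) \code{nPairs} counts the overlapping
#' displacement pairs at each lag; for an ensemble curve
#' (\code{kind = "ensemble"}) it counts the trajectories contributing at each
#' lag.
#'
#' @slot tau time delays in seconds, strictly increasing multiples of the
#'   frame interval.
#' @slot msd MSD values in square micrometres.
#' @slot nPairs integer counts per lag (displacement pairs or contributing
#'   trajectories, depending on \code{kind}).
#' @slot kind \code{"time_averaged"} or \code{"ensemble"}.
#'
#' @seealso \code{\link{computeTAMSD}}, \code{\link{computeEnsembleMSD}},
#'   \code{\link{fitDeff}}, \code{\link{fitAlpha}}
#' @export
setClass("MSDCurve",
  representation(
    tau = "numeric",
    msd = "numeric",
    nPairs = "integer",
    kind = "character"
  )
)

setValidity("MSDCurve", function(object) {
  msg <- character(0)
  n <- length(object@tau)
  if (length(object@msd) != n || length(object@nPairs) != n)
    msg <- c(msg, "tau, msd and nPairs must have equal length")
  if (n > 0) {
    if (any(object@tau <= 0) || any(diff(object@tau) <= 0))
      msg <- c(msg, "tau must be strictly increasing and positive")
    dt <- object@tau[1]
    if (any(abs(object@tau / dt - round(object@tau / dt)) > 1e-8))
      msg <- c(msg, "tau must be multiples of the frame interval")
    if (any(object@msd < 0))
      msg <- c(msg, "msd must be non-negative")
  }
  if (!object@kind %in% c("time_averaged", "ensemble"))
    msg <- c(msg, "kind must be 'time_averaged' or 'ensemble'")
  if (length(msg)) msg else TRUE
})

#' RheologyFit: diffusivity and anomalous-exponent fit results
#'
#' Result of fitting an MSD curve. \code{fitDeff} fills \code{Deff} with the
#' effective diffusion coefficient from the through-origin linear model
#' MSD = 4*Deff*tau (\code{alpha} is \code{NA}); \code{fitAlpha} fills
#' \code{alpha} with the log-log slope and \code{Deff} with the generalized
#' diffusion coefficient D from MSD = 4*D*tau^alpha (units um^2/s^alpha).
#'
#' @slot Deff effective (or generalized) diffusion coefficient.
#' @slot alpha anomalous diffusion exponent (NA for a pure linear fit).
#' @slot nLagsUsed number of lags entering the fit.
#' @slot rSquared coefficient of determination for the fitted model.
#' @slot scope \code{"trajectory"} or \code{"ensemble"}.
#' @export
setClass("RheologyFit",
  representation(
    Deff = "numeric",
    alpha = "numeric",
    nLagsUsed = "integer",
    rSquared = "numeric",
    scope = "character"
  ),
  prototype(alpha = NA_real_, scope = "trajectory")
)

setValidity("RheologyFit", function(object) {
  msg <- character(0)
  if (!object@scope %in% c("trajectory", "ensemble"))
    msg <- c(msg, "scope must be 'trajectory' or 'ensemble'")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of a simulated tracking experiment
#'
#' Parameters for simulating an ensemble of 2D tracer trajectories moving by
#' fractional Brownian motion (fBm). Each coordinate follows an independent
#' fBm with Hurst exponent \code{alpha/2}, so the noise-free 2D MSD is
#' 4*D*tau^alpha; static localization noise of standard deviation
#' \code{locError} micrometres is added independently to every coordinate of
#' every localization. Defaults reproduce a typical yeast-cytoplasm
#' acquisition: 500 ms frame interval, 0.18 um pixels, 2-minute movies
#' (240 frames).
#'
#' @slot nTrajectories number of trajectories.
#' @slot nFrames localizations per trajectory (>= 2).
#' @slot frameInterval frame interval in seconds.
#' @slot pixelSize pixel size in micrometres (used when rendering).
#' @slot D generalized diffusion coefficient, um^2/s^alpha.
#' @slot alpha anomalous exponent in (0, 2); 1 is Brownian.
#' @slot locError localization noise standard deviation per coordinate, um.
#' @slot fov square field-of-view width in pixels (start positions are
#'   uniform over the field).
#' @slot seed integer seed controlling all randomness of the simulation.
#' @export
setClass("SimulationConfig",
  representation(
    nTrajectories = "integer",
    nFrames = "integer",
    frameInterval = "numeric",
    pixelSize = "numeric",
    D = "numeric",
    alpha = "numeric",
    locError = "numeric",
    fov = "integer",
    seed = "integer"
  ),
  prototype(
    nTrajectories = 100L, nFrames = 240L, frameInterval = 0.5,
    pixelSize = 0.18, D = 0.01, alpha = 1, locError = 0,
    fov = 200L, seed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@alpha <= 0 || object@alpha >= 2)
    msg <- c(msg, "alpha must lie in (0, 2)")
  if (object@D < 0) msg <- c(msg, "D must be non-negative")
  if (object@locError < 0) msg <- c(msg, "locError must be non-negative")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be at least 2")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be positive")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@nTrajectories < 0L) msg <- c(msg, "nTrajectories must be >= 0")
  if (object@fov < 1L) msg <- c(msg, "fov must be >= 1 pixel")
  if (length(msg)) msg else TRUE
})

#' RenderConfig: parameters for rendering trajectories into a movie
#'
#' Controls how simulated trajectories are rasterized into a synthetic
#' fluorescence movie: particles are drawn as 2D Gaussians of width
#' \code{psfSigma} pixels at their subpixel positions, on a constant
#' background, with optional Poisson or Gaussian camera noise. Per-particle
#' peak intensities are drawn from a log-normal distribution with median
#' \code{peakIntensity} and log-sd \code{peakSdLog}, emulating heterogeneous
#' particle brightness; \code{peakSdLog = 0} gives identical particles.
#'
#' @slot psfSigma Gaussian PSF standard deviation, pixels.
#' @slot peakIntensity median peak amplitude, counts.
#' @slot peakSdLog log-sd of the per-particle peak amplitude distribution.
#' @slot background constant background level, counts.
#' @slot noiseModel \code{"none"}, \code{"poisson"} or \code{"gaussian"}.
#' @slot noiseSd Gaussian read-noise standard deviation, counts (used only
#'   when \code{noiseModel == "gaussian"}).
#' @slot bitDepth bit depth of the written TIFF (values clipped to range).
#' @export
setClass("RenderConfig",
  representation(
    psfSigma = "numeric",
    peakIntensity = "numeric",
    peakSdLog = "numeric",
    background = "numeric",
    noiseModel = "character",
    noiseSd = "numeric",
    bitDepth = "integer"
  ),
  prototype(
    psfSigma = 1.2, peakIntensity = 1000, peakSdLog = 0,
    background = 100, noiseModel = "none", noiseSd = 10, bitDepth = 16L
  )
)

setValidity("RenderConfig", function(object) {
  msg <- character(0)
  if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be positive")
  if (object@background < 0) msg <- c(msg, "background must be non-negative")
  if (!object@noiseModel %in% c("none", "poisson", "gaussian"))
    msg <- c(msg, "noiseModel must be 'none', 'poisson' or 'gaussian'")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' TrackingParams: spot-detection and linking parameters
#'
#' Parameter semantics follow the convention of particle trackers used for
#' in-cell microrheology: candidate spots are local intensity maxima within a
#' (2*radius+1) square neighbourhood that exceed the frame's
#' (100 - percentile) intensity quantile, refined to subpixel precision by an
#' intensity-weighted centroid over the radius-r disk. Linking assigns
#' detections frame-to-frame among pairs closer than \code{maxDisp} pixels,
#' minimizing squared displacement (Brownian cost). \code{linkRange = 1}
#' means no gap closing: a particle missing in one frame terminates its
#' trajectory. \code{cutoff = 0} disables any non-particle discrimination
#' score filter.
#'
#' @slot radius detection radius in pixels (neighbourhood and centroid disk).
#' @slot cutoff non-particle discrimination threshold; only 0 (disabled) is
#'   implemented.
#' @slot percentile percent of image intensity treated as candidate spots
#'   (threshold at the (100 - percentile) quantile); must be set per movie.
#' @slot linkRange number of frames over which links may be made; only 1
#'   (no gap closing) is implemented.
#' @slot maxDisp maximum frame-to-frame displacement in pixels.
#' @slot method assignment method, \code{"greedy"} (ascending-distance) or
#'   \code{"hungarian"} (optimal).
#' @export
setClass("TrackingParams",
  representation(
    radius = "integer",
    cutoff = "numeric",
    percentile = "numeric",
    linkRange = "integer",
    maxDisp = "numeric",
    method = "character"
  ),
  prototype(
    radius = 2L, cutoff = 0, percentile = 0.5,
    linkRange = 1L, maxDisp = 5, method = "greedy"
  )
)

setValidity("TrackingParams", function(object) {
  msg <- character(0)
  if (object@radius < 1L) msg <- c(msg, "radius must be >= 1")
  if (object@percentile <= 0 || object@percentile > 100)
    msg <- c(msg, "percentile must lie in (0, 100]")
  if (object@linkRange < 1L) msg <- c(msg, "linkRange must be >= 1")
  if (object@maxDisp <= 0) msg <- c(msg, "maxDisp must be positive")
  if (!object@method %in% c("greedy", "hungarian"))
    msg <- c(msg, "method must be 'greedy' or 'hungarian'")
  if (length(msg)) msg else TRUE
})

#' Movie: a stack of grayscale frames with acquisition metadata
#'
#' Frames are stored as a numeric array indexed \code{[row, column, frame]}
#' (row = y, column = x, both 0-based in the coordinate convention used by
#' the tracking functions: a pixel's centre is at its 0-based index).
#'
#' @slot frames numeric array, dim = c(height, width, nFrames).
#' @slot pixelSize micrometres per pixel.
#' @slot frameInterval seconds per frame.
#' @export
setClass("Movie",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameInterval = "numeric"
  )
)

setValidity("Movie", function(object) {
  msg <- character(0)
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "frames must be a 3D array [row, col, frame]")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be positive")
  if (length(msg)) msg else TRUE
})

#' ConditionSummary: per-condition, per-replicate summary statistics
#'
#' Medians of the per-trajectory effective diffusion coefficient and
#' anomalous exponent for one experimental condition and replicate, together
#' with the per-trajectory average mean intensities and the full
#' per-trajectory fit table.
#'
#' @slot condition condition label.
#' @slot replicate replicate label.
#' @slot nTrajectories number of trajectories entering the summary.
#' @slot medianDeff median per-trajectory D_eff, um^2/s.
#' @slot medianAlpha median per-trajectory alpha (NA if none could be fit).
#' @slot intensities per-trajectory average mean intensities (may be empty).
#' @slot records the per-trajectory fit table the medians were taken over.
#' @export
setClass("ConditionSummary",
  representation(
    condition = "character",
    replicate = "character",
    nTrajectories = "integer",
    medianDeff = "numeric",
    medianAlpha = "numeric",
    intensities = "numeric",
    records = "data.frame"
  )
)

setValidity("ConditionSummary", function(object) {
  msg <- character(0)
  if (object@nTrajectories != nrow(object@records))
    msg <- c(msg, "nTrajectories must equal nrow(records)")
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: replicate-paired comparison of two conditions
#'
#' Per-replicate fold changes of the condition medians (test over reference),
#' their mean and SD across replicates, and a paired two-tailed t-test. Two
#' labelled tests are reported because either construction is defensible for
#' small replicate designs: \code{tStatistic}/\code{pValue} test the paired
#' raw medians against each other, and \code{tStatisticFold}/
#' \code{pValueFold} test the per-replicate fold changes against 1. With all
#' per-replicate differences exactly zero the t statistic is undefined; the
#' result is flagged \code{degenerate} rather than silently assigned.
#'
#' @slot foldChanges per-replicate fold changes (test / reference).
#' @slot meanFold mean of the per-replicate fold changes.
#' @slot sdFold SD of the per-replicate fold changes.
#' @slot tStatistic paired t statistic on the raw per-replicate values.
#' @slot pValue two-sided p-value of the paired t-test.
#' @slot tStatisticFold one-sample t statistic of fold changes against 1.
#' @slot pValueFold two-sided p-value of the fold-change test.
#' @slot test description of the primary test.
#' @slot degenerate TRUE when the paired differences have zero variance.
#' @export
setClass("ComparisonResult",
  representation(
    foldChanges = "numeric",
    meanFold = "numeric",
    sdFold = "numeric",
    tStatistic = "numeric",
    pValue = "numeric",
    tStatisticFold = "numeric",
    pValueFold = "numeric",
    test = "character",
    degenerate = "logical"
  ),
  prototype(test = "paired two-tailed t", degenerate = FALSE)
)
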