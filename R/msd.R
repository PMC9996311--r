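## MSD quantification and short-timescale fits.
##
## Conventions: tau = k * frameInterval for integer lags k >= 1; the
## time-averaged MSD uses all overlapping displacement pairs; the effective
## diffusion coefficient comes from the through-origin model
## MSD(tau) = 4 * Deff * tau over the first ten lags (5 s at a 500 ms frame
## interval), and the anomalous exponent from an OLS fit of log10(MSD) on
## log10(tau) over the same window.

#' Filter trajectories by minimum length
#'
#' Keeps trajectories with at least \code{minPoints} localizations. The
#' default of 11 encodes the "more than ten time points" selection rule used
#' to limit tracking error in short spurious tracks. The counts of kept and
#' dropped trajectories are attached as the \code{"filterCounts"} attribute
#' and reported via \code{message}.
#'
#' @param x a \code{\linkS4class{TrajectorySet}}.
#' @param minPoints minimum number of localizations (default 11).
#' @param quiet suppress the count message.
#' @return the filtered \code{TrajectorySet}.
#' @examples
#' ts <- simulateCondition(SimulationConfig(nTrajectories = 3, nFrames = 30))
#' filterTrajectories(ts, minPoints = 11, quiet = TRUE)
#' @export
filterTrajectories <- function(x, minPoints = 11, quiet = FALSE) {
  stopifnot(is(x, "TrajectorySet"))
  len <- trajectoryLengths(x)
  keep <- names(len)[len >= minPoints]
  d <- x@data[x@data$trajectory_id %in% keep, , drop = FALSE]
  rownames(d) <- NULL
  out <- new("TrajectorySet", data = d, pixelSize = x@pixelSize,
             frameInterval = x@frameInterval)
  counts <- c(kept = length(keep), dropped = length(len) - length(keep))
  attr(out, "filterCounts") <- counts
  if (!quiet)
    message(sprintf("filterTrajectories: kept %d, dropped %d (minPoints = %d)",
                    counts["kept"], counts["dropped"], minPoints))
  out
}

# TA-MSD core on coordinate vectors; all overlapping pairs at each lag
.tamsd <- function(x, y, maxLag) {
  n <- length(x)
  k <- seq_len(maxLag)
  msd <- vapply(k, function(kk) {
    dx <- x[(kk + 1):n] - x[1:(n - kk)]
    dy <- y[(kk + 1):n] - y[1:(n - kk)]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  list(msd = msd, nPairs = n - k)
}

#' @describeIn computeTAMSD single-trajectory method. The trajectory must be
#'   gapless (consecutive frames); \code{maxLag} defaults to the largest
#'   available lag capped at 100.
#' @param maxLag largest lag (in frames) to evaluate.
#' @param frameInterval frame interval in seconds (data.frame method only).
#' @examples
#' tr <- data.frame(frame = 0:3, x_um = c(0, 1, 2, 3), y_um = 0)
#' msd(computeTAMSD(tr, frameInterval = 1))   # 1 4 9
#' @export
setMethod("computeTAMSD", "data.frame",
  function(x, maxLag = NULL, frameInterval = 0.5) {
    n <- nrow(x)
    if (n < 2) stop("trajectory needs at least 2 points")
    if (any(diff(x$frame) != 1))
      stop("trajectory has frame gaps; TA-MSD requires consecutive frames")
    if (is.null(maxLag)) maxLag <- min(n - 1L, 100L)
    if (maxLag > n - 1L)
      stop(sprintf("maxLag = %d exceeds available lags (%d)", maxLag, n - 1L))
    r <- .tamsd(x$x_um, x$y_um, maxLag)
    MSDCurve(seq_len(maxLag) * frameInterval, r$msd, r$nPairs,
             kind = "time_averaged")
  })

#' @describeIn computeTAMSD per-trajectory curves for a whole set; returns a
#'   named list of \code{MSDCurve}s. Trajectories shorter than
#'   \code{maxLag + 1} are evaluated up to their own largest lag.
#' @export
setMethod("computeTAMSD", "TrajectorySet",
  function(x, maxLag = NULL) {
    dt <- frameInterval(x)
    lapply(splitTrajectories(x), function(tr) {
      ml <- if (is.null(maxLag)) NULL else min(maxLag, nrow(tr) - 1L)
      computeTAMSD(tr, maxLag = ml, frameInterval = dt)
    })
  })

#' Ensemble-time-averaged MSD
#'
#' At each lag, the unweighted mean of the per-trajectory time-averaged MSD
#' values over all trajectories long enough to contribute that lag (a
#' trajectory of N points contributes lags up to N - 1). \code{nPairs}
#' records the number of contributing trajectories per lag, which is
#' non-increasing in the lag. Apply \code{\link{filterTrajectories}} first to
#' reproduce the "more than ten time points" selection.
#'
#' @param x a \code{\linkS4class{TrajectorySet}}.
#' @param maxLag largest lag to evaluate (default: largest lag supported by
#'   the longest trajectory, capped at 100).
#' @return an \code{\linkS4class{MSDCurve}} of kind \code{"ensemble"}.
#' @export
computeEnsembleMSD <- function(x, maxLag = NULL) {
  stopifnot(is(x, "TrajectorySet"))
  if (nTrajectories(x) == 0) stop("empty TrajectorySet")
  len <- trajectoryLengths(x)
  if (is.null(maxLag)) maxLag <- min(max(len) - 1L, 100L)
  curves <- computeTAMSD(x, maxLag = maxLag)
  acc <- numeric(maxLag)
  cnt <- integer(maxLag)
  for (cv in curves) {
    k <- length(cv@msd)
    kk <- seq_len(min(k, maxLag))
    acc[kk] <- acc[kk] + cv@msd[kk]
    cnt[kk] <- cnt[kk] + 1L
  }
  keep <- cnt > 0
  MSDCurve(seq_len(maxLag)[keep] * frameInterval(x),
           acc[keep] / cnt[keep], cnt[keep], kind = "ensemble")
}

#' Effective diffusion coefficient from a short-time linear MSD fit
#'
#' Fits \code{MSD(tau) = 4 * Deff * tau} through the origin by least squares
#' over the first \code{nLags} lags (the default 10 lags at a 0.5 s frame
#' interval is the 5-second timescale, D_eff-5sec). The closed form of this
#' projection is \code{Deff = sum(tau * MSD) / (4 * sum(tau^2))}. A
#' free-intercept variant (\code{intercept = TRUE}, \code{Deff = slope/4})
#' is available to absorb the constant MSD offset contributed by
#' localization noise, but the through-origin form is the default model.
#'
#' R-squared is reported against the fitted model; for the through-origin
#' model it is the no-intercept definition (1 - RSS / sum(MSD^2)).
#'
#' @param msdCurve an \code{\linkS4class{MSDCurve}}.
#' @param nLags number of initial lags to fit (default 10).
#' @param intercept fit a free intercept instead of forcing the origin.
#' @param scope \code{"trajectory"} or \code{"ensemble"} (annotation only).
#' @return a \code{\linkS4class{RheologyFit}} with \code{Deff} in um^2/s.
#' @examples
#' curve <- MSDCurve(tau = (1:10) * 0.5, msd = 4 * (1:10) * 0.5,
#'                   nPairs = rep(50, 10))
#' Deff(fitDeff(curve))   # 1
#' @export
fitDeff <- function(msdCurve, nLags = 10, intercept = FALSE,
                    scope = "trajectory") {
  stopifnot(is(msdCurve, "MSDCurve"))
  if (length(msdCurve@tau) < nLags)
    stop(sprintf("MSD curve has %d lags; %d required",
                 length(msdCurve@tau), nLags))
  tt <- msdCurve@tau[seq_len(nLags)]
  mm <- msdCurve@msd[seq_len(nLags)]
  if (all(mm == 0)) {
    return(new("RheologyFit", Deff = 0, alpha = NA_real_,
               nLagsUsed = as.integer(nLags), rSquared = NA_real_,
               scope = scope))
  }
  if (intercept) {
    fit <- stats::lm(mm ~ tt)
    D <- unname(stats::coef(fit)[2]) / 4
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((mm - mean(mm))^2)
  } else {
    fit <- stats::lm(mm ~ tt + 0)
    D <- unname(stats::coef(fit)[1]) / 4
    # no-intercept definition: variation measured about zero
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum(mm^2)
  }
  new("RheologyFit", Deff = D, alpha = NA_real_,
      nLagsUsed = as.integer(nLags),
      rSquared = r2, scope = scope)
}

#' Anomalous exponent from a log-log MSD fit
#'
#' Ordinary least squares of \code{log10(MSD)} on \code{log10(tau)} over the
#' first \code{nLags} lags, matching the power-law model
#' \code{MSD(tau) = 4 * D * tau^alpha}: \code{alpha} is the slope and the
#' generalized coefficient \code{D = 10^intercept / 4} (um^2/s^alpha) is
#' stored in the \code{Deff} slot. All fitted MSD values must be strictly
#' positive; curves violating this are rejected (callers exclude such
#' trajectories from the alpha analysis and count them).
#'
#' @param msdCurve an \code{\linkS4class{MSDCurve}}.
#' @param nLags number of initial lags to fit (default 10).
#' @param scope \code{"trajectory"} or \code{"ensemble"} (annotation only).
#' @return a \code{\linkS4class{RheologyFit}} with \code{alpha} set.
#' @examples
#' curve <- MSDCurve(tau = (1:10) * 0.5, msd = ((1:10) * 0.5)^0.5,
#'                   nPairs = rep(50, 10))
#' alphaExponent(fitAlpha(curve))   # 0.5
#' @export
fitAlpha <- function(msdCurve, nLags = 10, scope = "trajectory") {
  stopifnot(is(msdCurve, "MSDCurve"))
  if (length(msdCurve@tau) < nLags)
    stop(sprintf("MSD curve has %d lags; %d required",
                 length(msdCurve@tau), nLags))
  tt <- msdCurve@tau[seq_len(nLags)]
  mm <- msdCurve@msd[seq_len(nLags)]
  if (any(mm <= 0))
    stop("non-positive MSD value in fit range; cannot fit log-log model")
  fit <- stats::lm(log10(mm) ~ log10(tt))
  cf <- stats::coef(fit)
  lm10 <- log10(mm)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lm10 - mean(lm10))^2)
  new("RheologyFit", Deff = 10^unname(cf[1]) / 4, alpha = unname(cf[2]),
      nLagsUsed = as.integer(nLags),
      rSquared = r2, scope = scope)
}

#' Per-trajectory rheology fits for a whole condition
#'
#' Applies the length filter, computes each trajectory's time-averaged MSD,
#' and fits the effective diffusion coefficient (through-origin linear model)
#' and anomalous exponent (log-log OLS) over the first \code{nLags} lags.
#' Trajectories with a non-positive MSD at a fitted lag are excluded from the
#' alpha fit only (alpha is \code{NA}); their count is attached as attribute
#' \code{"alphaExcluded"}.
#'
#' @param x a \code{\linkS4class{TrajectorySet}}.
#' @param nLags lags entering both fits (default 10).
#' @param minPoints trajectory length filter (default 11).
#' @param interceptD fit D_eff with a free intercept (default FALSE).
#' @return data.frame with columns \code{trajectory_id}, \code{n_points},
#'   \code{D_eff_um2_per_s}, \code{alpha}, \code{r_squared_D},
#'   \code{r_squared_alpha}.
#' @examples
#' ts <- simulateCondition(SimulationConfig(nTrajectories = 20,
#'                                          nFrames = 60, seed = 3))
#' head(analyzeTrajectories(ts))
#' @export
analyzeTrajectories <- function(x, nLags = 10, minPoints = 11,
                                interceptD = FALSE) {
  stopifnot(is(x, "TrajectorySet"))
  xf <- filterTrajectories(x, minPoints = minPoints, quiet = TRUE)
  trs <- splitTrajectories(xf)
  dt <- frameInterval(xf)
  nExcl <- 0L
  rows <- lapply(names(trs), function(id) {
    tr <- trs[[id]]
    ml <- min(nLags, nrow(tr) - 1L)
    cv <- computeTAMSD(tr, maxLag = ml, frameInterval = dt)
    if (ml < nLags)
      return(data.frame(trajectory_id = id, n_points = nrow(tr),
                        D_eff_um2_per_s = NA_real_, alpha = NA_real_,
                        r_squared_D = NA_real_, r_squared_alpha = NA_real_))
    fd <- fitDeff(cv, nLags = nLags, intercept = interceptD)
    a <- NA_real_; ra <- NA_real_
    if (all(cv@msd[seq_len(nLags)] > 0)) {
      fa <- fitAlpha(cv, nLags = nLags)
      a <- fa@alpha; ra <- fa@rSquared
    } else {
      nExcl <<- nExcl + 1L
    }
    data.frame(trajectory_id = id, n_points = nrow(tr),
               D_eff_um2_per_s = fd@Deff, alpha = a,
               r_squared_D = fd@rSquared, r_squared_alpha = ra)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trajectory_id = character(0), n_points = integer(0),
               D_eff_um2_per_s = numeric(0), alpha = numeric(0),
               r_squared_D = numeric(0), r_squared_alpha = numeric(0))
  rownames(out) <- NULL
  attr(out, "alphaExcluded") <- nExcl
  attr(out, "filterCounts") <- attr(xf, "filterCounts")
  out
}
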