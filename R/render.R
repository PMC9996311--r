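## Rasterize trajectories into a synthetic fluorescence movie: each particle
## is a 2D Gaussian of width psfSigma at its subpixel position, on a flat
## background, with optional Poisson or Gaussian camera noise.

#' Render a trajectory set into a synthetic movie
#'
#' One frame is produced per time point covered by the trajectories. Each
#' particle present in a frame is drawn as a 2D Gaussian
#' (\code{amplitude * exp(-((x - x0)^2 + (y - y0)^2) / (2 * psfSigma^2))})
#' evaluated at pixel centres, truncated at 4 sigma, at its subpixel
#' position; per-particle amplitudes are drawn once per trajectory from a
#' log-normal with median \code{peakIntensity} and log-sd \code{peakSdLog},
#' emulating heterogeneous particle brightness. A constant background and
#' the configured camera noise are added, values are clipped to the bit
#' depth, and particles outside the field are simply not drawn (clipped,
#' never wrapped).
#'
#' @param trajs a \code{\linkS4class{TrajectorySet}} in micrometres.
#' @param render a \code{\linkS4class{RenderConfig}}.
#' @param fov field-of-view width in pixels (square frames).
#' @param seed seed for brightness and noise draws (the trajectory
#'   randomness is fixed upstream).
#' @return a \code{\linkS4class{Movie}}.
#' @examples
#' ts <- simulateCondition(SimulationConfig(nTrajectories = 3, nFrames = 10,
#'                                          fov = 64, seed = 1))
#' mv <- renderMovie(ts, RenderConfig(noiseModel = "none"), fov = 64)
#' mv
#' @export
renderMovie <- function(trajs, render = RenderConfig(), fov = 200,
                        seed = 1) {
  stopifnot(is(trajs, "TrajectorySet"), is(render, "RenderConfig"))
  validObject(render)
  set.seed(seed)
  d <- trajectoryData(trajs)
  px <- pixelSize(trajs)
  fov <- as.integer(fov)
  if (nrow(d) == 0) {
    warning("empty trajectory set; rendering pure background")
    nf <- 1L
  } else {
    nf <- max(d$frame) + 1L
  }
  ids <- unique(d$trajectory_id)
  amp <- stats::setNames(
    render@peakIntensity *
      exp(stats::rnorm(length(ids), 0, render@peakSdLog)), ids)
  frames <- array(render@background, dim = c(fov, fov, nf))
  if (nrow(d) > 0) {
    s <- render@psfSigma
    ext <- ceiling(4 * s)
    xpix <- d$x_um / px
    ypix <- d$y_um / px
    for (i in seq_len(nrow(d))) {
      x0 <- xpix[i]; y0 <- ypix[i]
      if (x0 < -ext || x0 > fov - 1 + ext || y0 < -ext || y0 > fov - 1 + ext)
        next
      xs <- max(0L, floor(x0 - ext)):min(fov - 1L, ceiling(x0 + ext))
      ys <- max(0L, floor(y0 - ext)):min(fov - 1L, ceiling(y0 + ext))
      if (!length(xs) || !length(ys)) next
      gx <- exp(-(xs - x0)^2 / (2 * s^2))
      gy <- exp(-(ys - y0)^2 / (2 * s^2))
      patch <- amp[d$trajectory_id[i]] * outer(gy, gx)
      f <- d$frame[i] + 1L
      frames[ys + 1L, xs + 1L, f] <- frames[ys + 1L, xs + 1L, f] + patch
    }
  }
  if (render@noiseModel == "poisson") {
    frames[] <- stats::rpois(length(frames), lambda = frames)
  } else if (render@noiseModel == "gaussian") {
    frames[] <- frames + stats::rnorm(length(frames), sd = render@noiseSd)
  }
  maxVal <- 2^render@bitDepth - 1
  frames[] <- pmin(pmax(frames, 0), maxVal)
  Movie(frames, pixelSize = px, frameInterval = frameInterval(trajs))
}
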