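## Spot detection and frame-to-frame linking.
##
## Coordinate convention (fixed so simulate -> render -> track round-trips):
## pixel centres sit at integer 0-based coordinates, x = column index,
## y = row index. Conversion to micrometres multiplies by the pixel size.

# Disk offsets (pixel centres within Euclidean distance <= r of the origin)
.diskOffsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

# Local maxima of a matrix: pixels strictly greater than every neighbour in
# the (2r+1) square window (ties, e.g. in a constant image, yield none).
.localMaxima <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  isMax <- matrix(TRUE, nr, nc)
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0 && dx == 0) next
      shifted <- matrix(-Inf, nr, nc)
      ys <- max(1, 1 + dy):min(nr, nr + dy)
      xs <- max(1, 1 + dx):min(nc, nc + dx)
      shifted[ys, xs] <- img[ys - dy, xs - dx]
      isMax <- isMax & (img > shifted)
    }
  }
  which(isMax, arr.ind = TRUE)
}

#' Detect bright spots in one frame
#'
#' Candidate spots are local intensity maxima within a
#' \code{(2*radius+1)} square neighbourhood whose value exceeds the
#' \code{(100 - percentile)} intensity quantile of the frame. Each candidate
#' is refined to subpixel precision by an intensity-weighted centroid over
#' the disk of radius \code{radius}, iteratively re-centred on the refined
#' estimate (which removes the pixel-locking bias of a fixed integer-centred
#' window), computed on the frame after subtraction of its median (a robust
#' flat-background estimate); \code{mass} is the summed
#' background-subtracted intensity over
#' the same disk and \code{mean_intensity} the raw mean. Setting
#' \code{cutoff = 0} (the only supported value) disables any further
#' non-particle discrimination.
#'
#' @param img numeric matrix (one frame, \code{[row, col]}).
#' @param params a \code{\linkS4class{TrackingParams}}.
#' @return data.frame with columns \code{x_px}, \code{y_px} (0-based
#'   subpixel), \code{mass}, \code{mean_intensity}; zero rows when no maxima
#'   pass the threshold (e.g. a constant image).
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 10
#' detectSpots(img, TrackingParams(percentile = 1))
#' @export
detectSpots <- function(img, params = TrackingParams()) {
  if (!is.matrix(img)) stop("img must be a 2D matrix")
  stopifnot(is(params, "TrackingParams"))
  validObject(params)
  if (params@cutoff != 0)
    stop("only cutoff = 0 (discrimination filter disabled) is supported")
  r <- params@radius
  if (nrow(img) < 2 * r + 1 || ncol(img) < 2 * r + 1)
    stop("image smaller than the detection neighbourhood")
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      mass = numeric(0), mean_intensity = numeric(0))
  peaks <- .localMaxima(img, r)
  if (nrow(peaks) == 0) return(empty)
  thr <- stats::quantile(img, probs = (100 - params@percentile) / 100,
                         names = FALSE)
  vals <- img[peaks]
  peaks <- peaks[vals > thr, , drop = FALSE]
  if (nrow(peaks) == 0) return(empty)
  bg <- stats::median(img)
  nr <- nrow(img); nc <- ncol(img)
  # window of candidate pixels; the disk test is applied per iteration
  win <- expand.grid(dy = -(r + 1):(r + 1), dx = -(r + 1):(r + 1))
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    py <- peaks[i, 1]; px <- peaks[i, 2]   # 1-based matrix indices
    # 0-based coordinates of the window around the maximum
    ys0 <- py - 1 + win$dy; xs0 <- px - 1 + win$dx
    ok <- ys0 >= 0 & ys0 < nr & xs0 >= 0 & xs0 < nc
    ys0 <- ys0[ok]; xs0 <- xs0[ok]
    raw <- img[cbind(ys0 + 1, xs0 + 1)]
    w <- pmax(raw - bg, 0)
    # iterative centroid: re-centre the radius-r disk on the refined
    # estimate so the window is symmetric about the spot, removing the
    # pixel-locking bias of a fixed integer-centred disk
    ex <- px - 1; ey <- py - 1
    m <- 0; inDisk <- NULL
    for (it in 1:8) {
      inDisk <- (xs0 - ex)^2 + (ys0 - ey)^2 <= r^2
      m <- sum(w[inDisk])
      if (m <= 0) break
      nx <- sum(w[inDisk] * xs0[inDisk]) / m
      ny <- sum(w[inDisk] * ys0[inDisk]) / m
      shift <- max(abs(nx - ex), abs(ny - ey))
      ex <- nx; ey <- ny
      if (shift < 1e-3) break
    }
    if (m <= 0) return(NULL)
    data.frame(x_px = ex, y_px = ey, mass = m,
               mean_intensity = mean(raw[inDisk]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$y_px, res$x_px), , drop = FALSE]
}

## ---- assignment solvers -------------------------------------------------

# Greedy matching by ascending squared distance; candidates beyond maxDisp
# are never linked. Ties broken by (row index, column index) order, which is
# (previous-track id, detection order) -- deterministic.
.assignGreedy <- function(d2, maxD2) {
  n <- nrow(d2); m <- ncol(d2)
  cand <- which(d2 <= maxD2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(rep(NA_integer_, n))
  ord <- order(d2[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  rowFree <- rep(TRUE, n); colFree <- rep(TRUE, m)
  match <- rep(NA_integer_, n)
  for (i in seq_len(nrow(cand))) {
    ri <- cand[i, 1]; ci <- cand[i, 2]
    if (rowFree[ri] && colFree[ci]) {
      match[ri] <- ci
      rowFree[ri] <- FALSE
      colFree[ci] <- FALSE
    }
  }
  match
}

# Hungarian algorithm (shortest augmenting paths with potentials) on an
# n x m cost matrix with n <= m. Returns, for each row, the assigned
# column index. Column index 1 below is a dummy; real columns are 2..m+1.
.hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1)        # row currently assigned to each column (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2:(m + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

# Optimal assignment restricted to pairs within maxDisp: forbidden pairs get
# a large finite cost plus per-row dummy columns so every row can stay
# unmatched rather than take a forbidden link.
.assignHungarian <- function(d2, maxD2) {
  n <- nrow(d2); m <- ncol(d2)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  big <- maxD2 + 1
  cost <- pmin(d2, big)
  cost[d2 > maxD2] <- big
  # n dummy columns at cost = big let any row opt out of a forbidden link
  cost <- cbind(cost, matrix(big, n, n))
  match <- .hungarian(cost)
  match[match > m] <- NA_integer_
  match[!is.na(match) & d2[cbind(seq_len(n), match)] > maxD2] <- NA_integer_
  match
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame assignment between the detections of consecutive frames,
#' restricted to pairs within \code{maxDisp} pixels, minimizing squared
#' displacement (the natural cost for Brownian dynamics). With
#' \code{method = "greedy"} pairs are accepted in ascending-distance order
#' (ties broken by previous-track then detection order, so the result is
#' deterministic and independent of input row order); with
#' \code{method = "hungarian"} the summed squared displacement is minimized
#' exactly. \code{linkRange = 1} means no gap closing: an unmatched track
#' terminates and an unmatched detection starts a new trajectory.
#'
#' @param detections data.frame with columns \code{frame} (0-based),
#'   \code{x_px}, \code{y_px} and optionally \code{mass},
#'   \code{mean_intensity}; e.g. the row-bound output of
#'   \code{\link{detectSpots}} over frames.
#' @param params a \code{\linkS4class{TrackingParams}}.
#' @param pixelSize micrometres per pixel for the output coordinates.
#' @param frameInterval seconds per frame for the output metadata.
#' @return a \code{\linkS4class{TrajectorySet}} (coordinates in um). The
#'   \code{intensity} column carries \code{mean_intensity} when present.
#' @export
linkSpots <- function(detections, params = TrackingParams(),
                      pixelSize = 0.18, frameInterval = 0.5) {
  stopifnot(is(params, "TrackingParams"))
  if (params@linkRange != 1L)
    stop("only linkRange = 1 (no gap closing) is supported")
  emptySet <- TrajectorySet(
    data.frame(trajectory_id = character(0), frame = integer(0),
               x_um = numeric(0), y_um = numeric(0)),
    pixelSize = pixelSize, frameInterval = frameInterval)
  if (is.null(detections) || nrow(detections) == 0) return(emptySet)
  if (!"mean_intensity" %in% names(detections))
    detections$mean_intensity <- NA_real_
  detections <- detections[order(detections$frame,
                                 detections$y_px, detections$x_px), ,
                           drop = FALSE]
  frames <- sort(unique(detections$frame))
  byFrame <- split(detections, detections$frame)
  maxD2 <- params@maxDisp^2
  nextId <- 1L
  rows <- list()
  # active tracks: id, last x/y (px), last frame
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  lastFrame <- -Inf
  for (f in frames) {
    det <- byFrame[[as.character(f)]]
    nd <- nrow(det)
    if (f != lastFrame + 1L)
      act <- act[0, , drop = FALSE]   # gap in the frame series ends tracks
    assignedTo <- rep(NA_integer_, nd)   # track id per detection
    if (nrow(act) > 0 && nd > 0) {
      d2 <- outer(act$x, det$x_px, "-")^2 + outer(act$y, det$y_px, "-")^2
      match <- if (params@method == "hungarian")
        .assignHungarian(d2, maxD2) else .assignGreedy(d2, maxD2)
      ok <- !is.na(match)
      assignedTo[match[ok]] <- act$id[ok]
    }
    newIdx <- which(is.na(assignedTo))
    if (length(newIdx)) {
      assignedTo[newIdx] <- seq(nextId, length.out = length(newIdx))
      nextId <- nextId + length(newIdx)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = assignedTo, frame = f, x_px = det$x_px, y_px = det$y_px,
      intensity = det$mean_intensity)
    act <- data.frame(id = assignedTo, x = det$x_px, y = det$y_px)
    lastFrame <- f
  }
  d <- do.call(rbind, rows)
  TrajectorySet(
    data.frame(trajectory_id = sprintf("traj_%04d", d$id),
               frame = as.integer(d$frame),
               x_um = d$x_px * pixelSize, y_um = d$y_px * pixelSize,
               intensity = d$intensity),
    pixelSize = pixelSize, frameInterval = frameInterval)
}

#' Measure particle intensity along a trajectory
#'
#' For each tracked frame, the mean of the raw pixel values within Euclidean
#' distance \code{radius} (default 3, measured between pixel centres,
#' including the centre pixel) of the particle's rounded position; the
#' scalar summary is the unweighted mean of these per-frame means over all
#' tracked frames ("average mean intensity"). When the disk extends beyond
#' the field, the in-field portion is used and the result is flagged.
#'
#' @param movie a \code{\linkS4class{Movie}}.
#' @param traj single-trajectory data.frame with \code{frame} (0-based) and
#'   either \code{x_um}/\code{y_um} (converted via the movie's pixel size)
#'   or \code{x_px}/\code{y_px}.
#' @param radius disk radius in pixels (default 3).
#' @return list with \code{perFrame} (per-frame mean intensities),
#'   \code{average} (their mean) and \code{edgeClipped} (TRUE if any disk
#'   was clipped at the field edge).
#' @export
measureIntensity <- function(movie, traj, radius = 3) {
  stopifnot(is(movie, "Movie"))
  nf <- nFrames(movie)
  if (any(traj$frame < 0) || any(traj$frame >= nf))
    stop("trajectory frames outside the movie range")
  if (all(c("x_px", "y_px") %in% names(traj))) {
    xs <- traj$x_px; ys <- traj$y_px
  } else {
    xs <- traj$x_um / movie@pixelSize
    ys <- traj$y_um / movie@pixelSize
  }
  off <- .diskOffsets(radius)
  nr <- nrow(movie@frames); nc <- ncol(movie@frames)
  clipped <- FALSE
  perFrame <- vapply(seq_along(xs), function(i) {
    # rounded 0-based centre -> 1-based matrix indices
    cx <- round(xs[i]) + 1L; cy <- round(ys[i]) + 1L
    yy <- cy + off$dy; xx <- cx + off$dx
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    if (!all(ok)) clipped <<- TRUE
    if (!any(ok)) return(NA_real_)
    fr <- movie@frames[, , traj$frame[i] + 1L]
    mean(fr[cbind(yy[ok], xx[ok])])
  }, numeric(1))
  list(perFrame = perFrame, average = mean(perFrame, na.rm = TRUE),
       edgeClipped = clipped)
}

#' Track a movie end to end
#'
#' Runs \code{\link{detectSpots}} on every frame, links the detections with
#' \code{\link{linkSpots}}, and measures each trajectory's per-frame mean
#' intensity within a fixed disk (\code{intensityRadius}, default 3 px),
#' storing it in the \code{intensity} column.
#'
#' @param movie a \code{\linkS4class{Movie}}.
#' @param params a \code{\linkS4class{TrackingParams}}.
#' @param intensityRadius disk radius for intensity measurement, pixels.
#' @return a \code{\linkS4class{TrajectorySet}} in micrometres.
#' @export
trackMovie <- function(movie, params = TrackingParams(),
                       intensityRadius = 3) {
  stopifnot(is(movie, "Movie"))
  nf <- nFrames(movie)
  dets <- lapply(seq_len(nf), function(i) {
    d <- detectSpots(getFrame(movie, i), params)
    if (nrow(d)) d$frame <- i - 1L
    d
  })
  dets <- do.call(rbind, dets[vapply(dets, nrow, integer(1)) > 0])
  ts <- linkSpots(dets, params, pixelSize = movie@pixelSize,
                  frameInterval = movie@frameInterval)
  if (nrow(ts@data) == 0) return(ts)
  trs <- splitTrajectories(ts)
  d <- ts@data
  for (id in names(trs)) {
    mi <- measureIntensity(movie, trs[[id]], radius = intensityRadius)
    d$intensity[d$trajectory_id == id] <- mi$perFrame
  }
  new("TrajectorySet", data = d, pixelSize = ts@pixelSize,
      frameInterval = ts@frameInterval)
}
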