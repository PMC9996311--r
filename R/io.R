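## File formats. All tabular writers emit a versioned comment header
## ("# rheoSPT/<kind> v<major>.<minor>"); readers reject unknown major
## versions. Trajectory tables use the shared dialect
## trajectory_id,frame,x_um,y_um,intensity with 0-based frames and
## micrometre coordinates, so simulated and tracked data are
## interchangeable downstream.

.FORMAT_VERSION <- "1.0"

.formatHeader <- function(kind) {
  sprintf("# rheoSPT/%s v%s", kind, .FORMAT_VERSION)
}

.checkFormatHeader <- function(line, kind) {
  pat <- sprintf("^# rheoSPT/%s v(\\d+)\\.(\\d+)$", kind)
  m <- regmatches(line, regexec(pat, line))[[1]]
  if (length(m) == 0) return(invisible(NULL))  # headerless files accepted
  major <- as.integer(m[2])
  ours <- as.integer(strsplit(.FORMAT_VERSION, ".", fixed = TRUE)[[1]][1])
  if (major > ours)
    stop(sprintf("file format %s v%s.%s is newer than supported (v%s)",
                 kind, m[2], m[3], .FORMAT_VERSION))
  invisible(NULL)
}

#' Write a trajectory table to CSV
#'
#' Native dialect: a versioned comment line, then a CSV with header
#' \code{trajectory_id,frame,x_um,y_um,intensity} (frame 0-based integer,
#' coordinates in micrometres).
#'
#' @param x a \code{\linkS4class{TrajectorySet}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(x, path) {
  stopifnot(is(x, "TrajectorySet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.formatHeader("trajectories"), con)
  utils::write.csv(trajectoryData(x), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' Two dialects are supported. \code{"native"} is the package's own format
#' (see \code{\link{writeTrajectories}}). \code{"mosaic"} reads exports of
#' Mosaic-style trackers whose coordinates are in pixels: supply
#' \code{columns} mapping the required fields to the file's column names;
#' pixel coordinates are converted to micrometres with \code{pixelSize}.
#' Validation rejects missing columns, duplicate (trajectory, frame) pairs
#' and non-monotone frames, naming the offending row.
#'
#' @param path input file.
#' @param dialect \code{"native"} or \code{"mosaic"}.
#' @param pixelSize micrometres per pixel (used to convert mosaic-dialect
#'   pixel coordinates, and stored as metadata).
#' @param frameInterval seconds per frame (stored as metadata).
#' @param columns named character vector mapping
#'   \code{c(trajectory_id=, frame=, x=, y=)} (and optionally
#'   \code{intensity=}) to the file's column names (mosaic dialect only).
#' @return a \code{\linkS4class{TrajectorySet}}.
#' @export
readTrajectories <- function(path, dialect = c("native", "mosaic"),
                             pixelSize = 0.18, frameInterval = 0.5,
                             columns = c(trajectory_id = "Trajectory",
                                         frame = "Frame",
                                         x = "x", y = "y")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  .checkFormatHeader(first, "trajectories")
  d <- utils::read.csv(path, comment.char = "#",
                       stringsAsFactors = FALSE)
  if (dialect == "native") {
    need <- c("trajectory_id", "frame", "x_um", "y_um")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "))
    if (!"intensity" %in% names(d)) d$intensity <- NA_real_
  } else {
    need <- c("trajectory_id", "frame", "x", "y")
    miss <- setdiff(need, names(columns))
    if (length(miss))
      stop("columns mapping lacks: ", paste(miss, collapse = ", "))
    missFile <- setdiff(unname(columns[need]), names(d))
    if (length(missFile))
      stop("missing column(s) in file: ", paste(missFile, collapse = ", "))
    out <- data.frame(
      trajectory_id = as.character(d[[columns[["trajectory_id"]]]]),
      frame = as.integer(d[[columns[["frame"]]]]),
      x_um = d[[columns[["x"]]]] * pixelSize,
      y_um = d[[columns[["y"]]]] * pixelSize)
    out$intensity <- if ("intensity" %in% names(columns) &&
                         columns[["intensity"]] %in% names(d))
      d[[columns[["intensity"]]]] else NA_real_
    d <- out
  }
  key <- paste(d$trajectory_id, d$frame)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (trajectory_id, frame) at row %d: (%s, %d)",
                 dup[1], d$trajectory_id[dup[1]], d$frame[dup[1]]))
  if (anyNA(d$frame))
    stop("non-integer or missing frame value at row ",
         which(is.na(d$frame))[1])
  ts <- TrajectorySet(d, pixelSize = pixelSize,
                      frameInterval = frameInterval)
  validObject(ts)
  ts
}

#' Write a movie as a 16-bit TIFF stack with a YAML sidecar
#'
#' Frames are written as an unsigned multi-page TIFF (values clipped to the
#' bit range); the pixel size and frame interval go into a YAML sidecar
#' (\code{<path>.yaml} by default), since plain TIFF has no standard slot
#' for them.
#'
#' @param movie a \code{\linkS4class{Movie}}.
#' @param path TIFF output path.
#' @param yamlPath sidecar path (default \code{paste0(path, ".yaml")}).
#' @param bitDepth 8 or 16.
#' @return \code{path}, invisibly.
#' @export
writeMovie <- function(movie, path, yamlPath = paste0(path, ".yaml"),
                       bitDepth = 16) {
  stopifnot(is(movie, "Movie"))
  maxVal <- 2^bitDepth - 1
  pages <- lapply(seq_len(nFrames(movie)), function(i) {
    fr <- round(pmin(pmax(getFrame(movie, i), 0), maxVal))
    fr / maxVal    # tiff package expects [0, 1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bitDepth)
  yaml::write_yaml(list(format = paste0("rheoSPT/movie v", .FORMAT_VERSION),
                        pixel_size_um = pixelSize(movie),
                        frame_interval_s = frameInterval(movie),
                        n_frames = nFrames(movie),
                        bit_depth = as.integer(bitDepth)),
                   yamlPath)
  invisible(path)
}

#' Read a TIFF movie and its YAML sidecar
#'
#' @param path TIFF file.
#' @param yamlPath sidecar (default \code{paste0(path, ".yaml")}); when
#'   absent, \code{pixelSize}/\code{frameInterval} defaults are used.
#' @param pixelSize,frameInterval fallbacks when no sidecar exists.
#' @return a \code{\linkS4class{Movie}} in original count units.
#' @export
readMovie <- function(path, yamlPath = paste0(path, ".yaml"),
                      pixelSize = 0.18, frameInterval = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bitDepth <- 16L
  if (file.exists(yamlPath)) {
    meta <- yaml::read_yaml(yamlPath)
    if (!is.null(meta$format)) {
      v <- sub("^rheoSPT/movie v", "", meta$format)
      major <- suppressWarnings(as.integer(strsplit(v, ".", fixed = TRUE)[[1]][1]))
      if (!is.na(major) && major > 1L)
        stop("movie format newer than supported: ", meta$format)
    }
    pixelSize <- meta$pixel_size_um %||% pixelSize
    frameInterval <- meta$frame_interval_s %||% frameInterval
    bitDepth <- as.integer(meta$bit_depth %||% 16L)
  }
  maxVal <- 2^bitDepth - 1
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]   # collapse any channel dim
    frames[, , i] <- pg * maxVal
  }
  Movie(frames, pixelSize = pixelSize, frameInterval = frameInterval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-trajectory rheology results and an ensemble MSD table
#'
#' Both files are tab-separated with a versioned comment header; run
#' metadata (parameters, counts) goes to a YAML file alongside.
#'
#' @param records per-trajectory table from
#'   \code{\link{analyzeTrajectories}}.
#' @param ensembleMSD an ensemble \code{\linkS4class{MSDCurve}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param metadata named list written to the YAML run-metadata file.
#' @return named character vector of the written paths, invisibly.
#' @export
writeResults <- function(records, ensembleMSD, dir, prefix = "results",
                         metadata = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trajPath <- file.path(dir, paste0(prefix, "_per_trajectory.tsv"))
  con <- file(trajPath, "w")
  writeLines(.formatHeader("per_trajectory"), con)
  utils::write.table(records, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)
  msdPath <- file.path(dir, paste0(prefix, "_ensemble_msd.tsv"))
  con <- file(msdPath, "w")
  writeLines(.formatHeader("ensemble_msd"), con)
  utils::write.table(
    data.frame(tau_s = tau(ensembleMSD), msd_um2 = msd(ensembleMSD),
               n_contributing = nPairs(ensembleMSD)),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  metaPath <- file.path(dir, paste0(prefix, "_metadata.yaml"))
  yaml::write_yaml(c(list(format = paste0("rheoSPT/metadata v",
                                          .FORMAT_VERSION)), metadata),
                   metaPath)
  invisible(c(per_trajectory = trajPath, ensemble_msd = msdPath,
              metadata = metaPath))
}
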