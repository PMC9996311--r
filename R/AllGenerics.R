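#' @rdname TrajectorySet-accessors
#' @export
setGeneric("trajectoryData", function(x) standardGeneric("trajectoryData"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("trajectoryLengths", function(x) standardGeneric("trajectoryLengths"))

#' @rdname MSDCurve-accessors
#' @export
setGeneric("tau", function(x) standardGeneric("tau"))

#' @rdname MSDCurve-accessors
#' @export
setGeneric("msd", function(x) standardGeneric("msd"))

#' @rdname MSDCurve-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname RheologyFit-accessors
#' @export
setGeneric("Deff", function(x) standardGeneric("Deff"))

#' @rdname RheologyFit-accessors
#' @export
setGeneric("alphaExponent", function(x) standardGeneric("alphaExponent"))

#' Compute the time-averaged MSD
#'
#' @param x a single-trajectory \code{data.frame} (columns \code{frame},
#'   \code{x_um}, \code{y_um}) or a \code{TrajectorySet}.
#' @param ... passed to methods.
#' @export
setGeneric("computeTAMSD", function(x, ...) standardGeneric("computeTAMSD"))

#' Fold change of median effective diffusion coefficients
#'
#' @param test,reference \code{ConditionSummary} objects (or bare numbers).
#' @export
setGeneric("foldChange",
           function(test, reference) standardGeneric("foldChange"))
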