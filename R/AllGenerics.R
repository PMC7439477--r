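#' @include AllClasses.R
NULL

#' Accessors for FrameStack and TrackSet
#'
#' @param x a [FrameStack-class] or [TrackSet-class] object.
#' @param i frame index (1-based).
#' @name accessors
NULL

#' @rdname accessors
#' @return `pixelSize()`: micrometers per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @return `frameInterval()`: seconds per frame.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @return `nFrames()`: number of frames.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @return `getFrame()`: one frame as a numeric matrix (row, col).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname accessors
#' @return `groundTruth()`: the ground-truth data frame (zero rows if absent).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @return `trackPoints()`: the per-detection data frame of a TrackSet.
#' @export
setGeneric("trackPoints", function(x) standardGeneric("trackPoints"))

#' @rdname accessors
#' @return `nTracks()`: number of distinct tracks.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' Per-track summary statistics
#'
#' @param x a [TrackSet-class].
#' @return `trackSummary()`: data frame with one row per track: `track_id`,
#'   `n_frames`, `first_frame`, `mean_x`, `mean_y` (micrometers) and
#'   `mean_speed` (micrometers/second; `NA` for single-point tracks).
#' @export
setGeneric("trackSummary", function(x) standardGeneric("trackSummary"))

#' @rdname trackSummary
#' @return `trackSpeeds()`: named numeric vector of mean per-step speeds
#'   (micrometers/second), one entry per track.
#' @export
setGeneric("trackSpeeds", function(x) standardGeneric("trackSpeeds"))

setMethod("pixelSize", "FrameStack", function(x) x@pixelSize)
setMethod("frameInterval", "FrameStack", function(x) x@frameInterval)
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3L])
setMethod("getFrame", "FrameStack", function(x, i) x@frames[, , i])
setMethod("groundTruth", "FrameStack", function(x) x@groundTruth)

setMethod("pixelSize", "TrackSet", function(x) x@pixelSize)
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)
setMethod("trackPoints", "TrackSet", function(x) x@points)
setMethod("nTracks", "TrackSet", function(x) length(unique(x@points$track_id)))

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat("FrameStack:", d[2], "x", d[1], "px,", d[3], "frames\n")
  cat("  pixel size:", object@pixelSize, "um/px; frame interval:",
      object@frameInterval, "s (", round(1 / object@frameInterval, 2), "fps )\n")
  cat("  duration:", round((d[3] - 1) * object@frameInterval, 2), "s\n")
  gt <- object@groundTruth
  if (nrow(gt) > 0) {
    cells <- unique(gt[, c("cell_id", "is_motile")])
    cat("  ground truth:", nrow(cells), "cells (",
        sum(cells$is_motile), "motile )\n")
  }
  invisible(NULL)
})

setMethod("show", "TrackSet", function(object) {
  n <- nTracks(object)
  cat("TrackSet:", n, "tracks,", nrow(object@points), "points\n")
  if (n > 0) {
    len <- table(object@points$track_id)
    cat("  track length (frames): median", stats::median(len),
        "range", min(len), "-", max(len), "\n")
  }
  invisible(NULL)
})
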