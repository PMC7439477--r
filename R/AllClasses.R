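#' FrameStack: a calibrated grayscale movie
#'
#' Container for a time-lapse microscopy movie held as a 3-D intensity array
#' (row, column, frame) together with its spatial and temporal calibration.
#' Movies produced by [simulateMovie()] additionally carry the ground-truth
#' cell trajectories used to validate detection and tracking.
#'
#' Coordinate convention: the origin lies at the center of pixel `[1, 1]`;
#' `x` increases with column and `y` with row, so a subpixel position in
#' micrometers is `(index - 1) * pixelSize`. Frames are indexed from 1.
#'
#' @slot frames numeric array, `dim = c(height_px, width_px, n_frames)`;
#'   intensities are finite and non-negative.
#' @slot pixelSize pixel edge length in micrometers per pixel.
#' @slot frameInterval time between consecutive frames in seconds.
#' @slot groundTruth data frame with columns `cell_id`, `frame`, `x_um`,
#'   `y_um`, `is_motile`, `true_speed_um_s` (zero rows when unknown).
#' @slot metadata list of generator parameters (including the seed) or
#'   acquisition notes.
#'
#' @seealso [simulateMovie()], [detectStack()], [readFrameStack()]
#' @export
setClass("FrameStack",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameInterval = "numeric",
    groundTruth = "data.frame",
    metadata = "list"
  ),
  prototype(
    frames = array(0, dim = c(1, 1, 1)),
    pixelSize = 0.325,
    frameInterval = 0.05,
    groundTruth = data.frame(),
    metadata = list()
  )
)

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "frames must be a 3-D array (row, col, frame) with positive extents")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um/px)")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number (s)")
  if (anyNA(object@frames) || !all(is.finite(range(object@frames))))
    msg <- c(msg, "frame intensities must all be finite")
  else if (min(object@frames) < 0)
    msg <- c(msg, "frame intensities must be non-negative")
  gt <- object@groundTruth
  if (nrow(gt) > 0) {
    need <- c("cell_id", "frame", "x_um", "y_um", "is_motile", "true_speed_um_s")
    if (!all(need %in% names(gt)))
      msg <- c(msg, paste("groundTruth must have columns:",
                          paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FrameStack
#'
#' @param frames 3-D numeric array (row, col, frame); a single matrix is
#'   promoted to a one-frame stack.
#' @param pixelSize pixel size in micrometers per pixel.
#' @param frameInterval frame interval in seconds.
#' @param groundTruth optional ground-truth data frame (see the class doc).
#' @param metadata optional list of parameters/notes.
#' @return A [FrameStack-class] object.
#' @examples
#' fs <- FrameStack(array(1, c(8, 8, 2)), pixelSize = 0.325, frameInterval = 0.05)
#' nFrames(fs)
#' @export
FrameStack <- function(frames, pixelSize, frameInterval,
                       groundTruth = data.frame(), metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  new("FrameStack", frames = frames, pixelSize = pixelSize,
      frameInterval = frameInterval, groundTruth = groundTruth,
      metadata = metadata)
}

#' TrackSet: linked particle trajectories
#'
#' Time-ordered subpixel positions of tracked objects, one row per detection,
#' grouped by `track_id`. Tracks contain no gaps: within a track, frame
#' indices increase in steps of exactly 1 (a missed detection terminates a
#' track rather than being bridged).
#'
#' @slot points data frame with columns `track_id`, `frame`, `x`, `y`
#'   (positions in micrometers) and optionally `intensity`.
#' @slot pixelSize micrometers per pixel of the source movie.
#' @slot frameInterval seconds per frame of the source movie.
#'
#' @seealso [linkNearestNeighbor()], [filterTracks()], [trackSummary()]
#' @export
setClass("TrackSet",
  representation(
    points = "data.frame",
    pixelSize = "numeric",
    frameInterval = "numeric"
  ),
  prototype(
    points = data.frame(track_id = integer(), frame = integer(),
                        x = numeric(), y = numeric()),
    pixelSize = 0.325,
    frameInterval = 0.05
  )
)

setValidity("TrackSet", function(object) {
  msg <- character()
  p <- object@points
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("points must have columns:", paste(need, collapse = ", ")))
  else if (nrow(p) > 1) {
    o <- order(p$track_id, p$frame)
    same <- p$track_id[o][-1] == p$track_id[o][-nrow(p)]
    dfr <- diff(p$frame[o])
    if (any(same & dfr != 1L))
      msg <- c(msg, "within a track, frames must increase in steps of exactly 1")
  }
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number (s)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um/px)")
  if (length(msg)) msg else TRUE
})

#' Construct a TrackSet
#'
#' @param points data frame with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `intensity`.
#' @param pixelSize micrometers per pixel.
#' @param frameInterval seconds per frame.
#' @return A [TrackSet-class] object.
#' @export
TrackSet <- function(points, pixelSize, frameInterval) {
  points <- points[order(points$track_id, points$frame), , drop = FALSE]
  rownames(points) <- NULL
  new("TrackSet", points = points, pixelSize = pixelSize,
      frameInterval = frameInterval)
}
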