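# File interfaces: multi-page 16-bit grayscale TIFF for movies, plain CSV
# for detections, tracks, ground truth, count tables and trajectories.

#' Write a movie to a multi-page 16-bit grayscale TIFF
#'
#' Intensities are rounded to integers and clipped to the 16-bit range
#' \[0, 65535\]; calibration is not stored in the file and must be supplied
#' again when reading.
#'
#' @param stack a [FrameStack-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  pages <- lapply(seq_len(nFrames(stack)), function(i) {
    m <- pmin(pmax(round(getFrame(stack, i)), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a FrameStack
#'
#' @param path TIFF file (8- or 16-bit grayscale).
#' @param pixelSize micrometers per pixel.
#' @param frameInterval seconds per frame.
#' @return A [FrameStack-class]; intensities are returned on the original
#'   integer scale.
#' @export
readFrameStack <- function(path, pixelSize, frameInterval) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  toMat <- function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse replicated channels
    p * 65535
  }
  mats <- lapply(pages, toMat)
  frames <- array(unlist(mats), dim = c(nrow(mats[[1]]), ncol(mats[[1]]),
                                        length(mats)))
  FrameStack(frames, pixelSize = pixelSize, frameInterval = frameInterval)
}

#' CSV interchange for pipeline tables
#'
#' Thin wrappers around `write.csv`/`read.csv` fixing the column layouts of
#' the pipeline's tables: detections (`frame, x_um, y_um, intensity`),
#' track points (`track_id, frame, x_um, y_um`), ground truth
#' (`cell_id, frame, x_um, y_um, is_motile, true_speed_um_s`), competition
#' count tables and passage trajectories.
#'
#' @param detections,tracks,x object to write (for `writeTracks`, a
#'   [TrackSet-class]).
#' @param path CSV file path.
#' @param pixelSize,frameInterval calibration attached on read.
#' @name csv-io
NULL

#' @rdname csv-io
#' @export
writeDetections <- function(detections, path) {
  out <- data.frame(frame = detections$frame, x_um = detections$x,
                    y_um = detections$y, intensity = detections$intensity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readDetections <- function(path, pixelSize, frameInterval) {
  d <- utils::read.csv(path)
  out <- data.frame(frame = d$frame, x = d$x_um, y = d$y_um,
                    intensity = d$intensity)
  attr(out, "pixelSize") <- pixelSize
  attr(out, "frameInterval") <- frameInterval
  out
}

#' @rdname csv-io
#' @export
writeTracks <- function(tracks, path) {
  p <- trackPoints(tracks)
  out <- data.frame(track_id = p$track_id, frame = p$frame,
                    x_um = p$x, y_um = p$y)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readTracks <- function(path, pixelSize, frameInterval) {
  d <- utils::read.csv(path)
  TrackSet(data.frame(track_id = d$track_id, frame = d$frame,
                      x = d$x_um, y = d$y_um),
           pixelSize, frameInterval)
}

#' @rdname csv-io
#' @export
writeGroundTruth <- function(x, path) {
  utils::write.csv(groundTruth(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
writeCompetitionTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readCompetitionTable <- function(path) utils::read.csv(path)

#' @rdname csv-io
#' @export
writePassageTrajectory <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readPassageTrajectory <- function(path) utils::read.csv(path)

#' Plot a speed histogram
#'
#' Base-graphics bar rendering of a [speedHistogram()] table, with the
#' motile cutoff marked.
#'
#' @param h data frame from [speedHistogram()].
#' @param cutoff motile cutoff to mark (micrometers/second); `NULL` to omit.
#' @param ... further arguments to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plotSpeedHistogram <- function(h, cutoff = 2, ...) {
  if (nrow(h) == 0) stop("empty histogram")
  mids <- graphics::barplot(h$count, width = h$bin_hi - h$bin_lo,
                            space = 0, col = "grey70", border = "grey30",
                            xlab = "speed (um/s)", ylab = "tracks", ...)
  graphics::axis(1, at = seq(0, nrow(h), by = max(1, nrow(h) %/% 8)),
                 labels = h$bin_lo[1] +
                   seq(0, nrow(h), by = max(1, nrow(h) %/% 8)) *
                   (h$bin_hi[1] - h$bin_lo[1]))
  if (!is.null(cutoff))
    graphics::abline(v = cutoff / (h$bin_hi[1] - h$bin_lo[1]), lty = 2,
                     col = "red3")
  invisible(mids)
}
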