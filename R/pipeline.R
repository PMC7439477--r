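#' Run the full motility pipeline on one movie
#'
#' Convenience wrapper chaining the standard analysis of a single movie:
#' [detectStack()] (bandpass, threshold, radial-symmetry localization),
#' [linkNearestNeighbor()], [filterTracks()] (minimum length, duplicate
#' cull) and [speedRecords()].
#'
#' @param stack a [FrameStack-class].
#' @param flaskId,strain labels for the resulting records.
#' @param maxDisp linking gate in micrometers.
#' @param minFrames,dupDist track filters, see [filterTracks()].
#' @param cutoff motile cutoff in micrometers/second.
#' @param ... further arguments to [detectStack()] (thresholding, bandpass
#'   scales, `invert` for bright-field movies, ...).
#' @return data frame of per-track speed records (see [speedRecords()]).
#' @examples
#' fs <- simulateMovie(widthPx = 96, heightPx = 96, nFrames = 30, nCells = 8,
#'                     seed = 3)
#' rec <- motilityPipeline(fs, flaskId = "F1", strain = "ancestor")
#' classifyMotile(rec)
#' @export
motilityPipeline <- function(stack, flaskId, strain, maxDisp = 2,
                             minFrames = 5, dupDist = 1.7, cutoff = 2, ...) {
  det <- detectStack(stack, ...)
  tracks <- linkNearestNeighbor(det, maxDisp = maxDisp)
  tracks <- filterTracks(tracks, minFrames = minFrames, dupDist = dupDist)
  speedRecords(tracks, flaskId = flaskId, strain = strain, cutoff = cutoff)
}
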