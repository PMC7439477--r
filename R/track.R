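# Track assembly: greedy nearest-neighbor linking between consecutive
# frames, then the two track filters (minimum length, duplicate culling).

#' Link detections into tracks by nearest-neighbor assignment
#'
#' For each consecutive frame pair, candidate links (pairs within `maxDisp`)
#' are taken closest-pair-first, each detection used at most once; remaining
#' ties are broken by the (x, y) order of the linked detections, so the
#' result is deterministic. Detections that receive no link from the
#' previous frame start new tracks. No gap closing is performed: a missed
#' detection terminates its track.
#'
#' @param detections data frame from [detectStack()] (columns `frame`, `x`,
#'   `y`, optionally `intensity`), or any data frame with those columns.
#' @param maxDisp maximum link length in micrometers. The default gate
#'   should exceed the largest plausible per-frame displacement
#'   (speed x frame interval) by a safety factor; 2 um at 20 fps
#'   accommodates swimmers up to ~25 um/s.
#' @param pixelSize,frameInterval movie calibration; taken from the
#'   attributes [detectStack()] attaches when not supplied.
#' @return A [TrackSet-class]. Track ids are assigned in order of track
#'   creation (frame, then x, y).
#' @export
linkNearestNeighbor <- function(detections, maxDisp = 2,
                                pixelSize = attr(detections, "pixelSize"),
                                frameInterval = attr(detections, "frameInterval")) {
  stopifnotPositive(maxDisp = maxDisp)
  if (is.null(pixelSize) || is.null(frameInterval))
    stop("pixelSize and frameInterval must be supplied (or present as attributes)")
  det <- as.data.frame(detections)
  det <- det[order(det$frame, det$x, det$y), , drop = FALSE]
  n <- nrow(det)
  if (n == 0) {
    return(TrackSet(data.frame(track_id = integer(), frame = integer(),
                               x = numeric(), y = numeric()),
                    pixelSize, frameInterval))
  }
  trackId <- integer(n)
  byFrame <- split(seq_len(n), det$frame)
  frames <- as.integer(names(byFrame))
  nextId <- 0L
  prevIdx <- integer(0); prevFrame <- -1L
  for (fi in seq_along(frames)) {
    cur <- byFrame[[fi]]
    linkedTo <- rep(NA_integer_, length(cur))
    if (frames[fi] == prevFrame + 1L && length(prevIdx) > 0) {
      # all candidate links within the gate, closest first
      dx <- outer(det$x[prevIdx], det$x[cur], "-")
      dy <- outer(det$y[prevIdx], det$y[cur], "-")
      dmat <- sqrt(dx^2 + dy^2)
      ok <- which(dmat <= maxDisp, arr.ind = TRUE)
      if (nrow(ok) > 0) {
        dd <- dmat[ok]
        o <- order(dd, det$x[prevIdx[ok[, 1]]], det$y[prevIdx[ok[, 1]]],
                   det$x[cur[ok[, 2]]], det$y[cur[ok[, 2]]])
        usedPrev <- logical(length(prevIdx))
        usedCur <- logical(length(cur))
        for (e in o) {
          i <- ok[e, 1]; j <- ok[e, 2]
          if (!usedPrev[i] && !usedCur[j]) {
            usedPrev[i] <- TRUE; usedCur[j] <- TRUE
            linkedTo[j] <- prevIdx[i]
          }
        }
      }
    }
    for (k in seq_along(cur)) {
      if (is.na(linkedTo[k])) {
        nextId <- nextId + 1L
        trackId[cur[k]] <- nextId
      } else {
        trackId[cur[k]] <- trackId[linkedTo[k]]
      }
    }
    prevIdx <- cur; prevFrame <- frames[fi]
  }
  pts <- data.frame(track_id = trackId, frame = det$frame, x = det$x, y = det$y)
  if ("intensity" %in% names(det)) pts$intensity <- det$intensity
  TrackSet(pts, pixelSize, frameInterval)
}

#' Filter tracks by length and cull duplicate tracks
#'
#' Applies the two standard track filters: tracks spanning fewer than
#' `minFrames` frames are discarded; then tracks whose mean positions lie
#' within `dupDist` of one another — multiple short tracks repeatedly
#' spawned by the same non-motile cell — are grouped by single linkage and
#' only the longest track per group is kept (ties keep the earlier first
#' frame, then the lower track id). The operation is idempotent.
#'
#' Single-linkage grouping means chains merge: if A-B and B-C are each
#' within `dupDist`, all three are one group even when A-C is not. The
#' pairwise alternative can be obtained by pre-splitting the input.
#'
#' @param tracks a [TrackSet-class].
#' @param minFrames minimum track length in frames (default 5).
#' @param dupDist mean-position culling radius in micrometers (default 1.7);
#'   pairs at exactly `dupDist` are not grouped (strict `<`).
#' @return A filtered [TrackSet-class] (original track ids, sorted).
#' @export
filterTracks <- function(tracks, minFrames = 5, dupDist = 1.7) {
  stopifnot(is(tracks, "TrackSet"))
  stopifnotPositive(minFrames = minFrames, dupDist = dupDist)
  p <- trackPoints(tracks)
  if (nrow(p) == 0) return(tracks)
  sm <- trackSummary(tracks)
  sm <- sm[sm$n_frames >= minFrames, , drop = FALSE]
  if (nrow(sm) == 0)
    return(TrackSet(p[0, , drop = FALSE], pixelSize(tracks),
                    frameInterval(tracks)))
  if (nrow(sm) > 1) {
    d <- stats::dist(cbind(sm$mean_x, sm$mean_y))
    grp <- stats::cutree(stats::hclust(d, method = "single"),
                         h = dupDist - 1e-9)
  } else grp <- 1L
  keepIds <- vapply(split(seq_len(nrow(sm)), grp), function(ix) {
    g <- sm[ix, , drop = FALSE]
    g <- g[order(-g$n_frames, g$first_frame, g$track_id), , drop = FALSE]
    g$track_id[1]
  }, numeric(1))
  out <- p[p$track_id %in% keepIds, , drop = FALSE]
  TrackSet(out, pixelSize(tracks), frameInterval(tracks))
}

#' @rdname trackSummary
#' @export
setMethod("trackSummary", "TrackSet", function(x) {
  p <- x@points
  if (nrow(p) == 0)
    return(data.frame(track_id = integer(), n_frames = integer(),
                      first_frame = integer(), mean_x = numeric(),
                      mean_y = numeric(), mean_speed = numeric()))
  o <- order(p$track_id, p$frame)
  p <- p[o, , drop = FALSE]
  ids <- unique(p$track_id)
  nfr <- as.integer(table(factor(p$track_id, levels = ids)))
  sp <- trackSpeeds(x)
  data.frame(
    track_id = ids,
    n_frames = nfr,
    first_frame = as.integer(tapply(p$frame, factor(p$track_id, levels = ids), min)),
    mean_x = as.numeric(tapply(p$x, factor(p$track_id, levels = ids), mean)),
    mean_y = as.numeric(tapply(p$y, factor(p$track_id, levels = ids), mean)),
    mean_speed = as.numeric(sp[as.character(ids)])
  )
})

#' @rdname trackSummary
#' @export
setMethod("trackSpeeds", "TrackSet", function(x) {
  p <- x@points
  ids <- unique(p$track_id)
  if (nrow(p) == 0) return(stats::setNames(numeric(0), character(0)))
  o <- order(p$track_id, p$frame)
  p <- p[o, , drop = FALSE]
  n <- nrow(p)
  sp <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (n > 1) {
    same <- p$track_id[-1] == p$track_id[-n]
    step <- sqrt(diff(p$x)^2 + diff(p$y)^2) / x@frameInterval
    step <- step[same]
    id <- p$track_id[-1][same]
    if (length(step)) {
      m <- tapply(step, id, mean)
      sp[names(m)] <- as.numeric(m)
    }
  }
  sp
})
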