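# Spot detection: difference-of-Gaussians bandpass -> intensity threshold ->
# radial-symmetry subpixel localization.

# Banded sparse convolution matrices (one per axis) give a separable Gaussian
# blur that is ~4x faster than FFT filtering at these frame sizes. Rows are
# renormalized where the kernel is truncated by the frame edge, so constants
# are preserved exactly everywhere (a constant frame bandpasses to zero,
# including at borders). Matrices are cached per (size, sigma).
.convCache <- new.env(parent = emptyenv())

gaussConvMat <- function(n, sigma) {
  key <- paste(n, sigma)
  if (!is.null(m <- .convCache[[key]])) return(m)
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  i <- rep(seq_len(n), each = 2L * r + 1L)
  j <- i + rep(-r:r, times = n)
  x <- rep(k, times = n)
  ok <- j >= 1L & j <= n
  m <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = x[ok], dims = c(n, n))
  m <- m / Matrix::rowSums(m)
  .convCache[[key]] <- m
  m
}

gaussBlur <- function(frame, sigma) {
  kr <- gaussConvMat(nrow(frame), sigma)
  kc <- gaussConvMat(ncol(frame), sigma)
  as.matrix(kr %*% frame %*% Matrix::t(kc))
}

#' Difference-of-Gaussians bandpass filter
#'
#' Suppresses pixel noise (scales below `sigmaNoise`) and slow background
#' variation (scales above `sigmaObject`), leaving diffraction-limited
#' spot-sized structure. The result is the Gaussian blur at `sigmaNoise`
#' minus the blur at `sigmaObject`, clipped at zero. Kernels are truncated
#' at four sigma and renormalized at frame edges so constant input maps to
#' exactly zero output.
#'
#' @param frame 2-D numeric intensity matrix (row, col).
#' @param sigmaNoise small blur scale in pixels (default 1).
#' @param sigmaObject large blur scale in pixels (default 4); must exceed
#'   `sigmaNoise`.
#' @return Filtered matrix, same shape as `frame`, non-negative.
#' @examples
#' bandpassFilter(matrix(5, 16, 16))[1:3, 1:3]  # constant -> 0
#' @export
bandpassFilter <- function(frame, sigmaNoise = 1, sigmaObject = 4) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  stopifnotPositive(sigmaNoise = sigmaNoise, sigmaObject = sigmaObject)
  if (sigmaNoise >= sigmaObject)
    stop("sigmaNoise must be strictly smaller than sigmaObject")
  pmax(gaussBlur(frame, sigmaNoise) - gaussBlur(frame, sigmaObject), 0)
}

#' Find candidate spots by thresholded local maxima
#'
#' Local maxima of a (typically bandpass-filtered) frame above an absolute
#' intensity threshold, with the brighter member kept whenever two maxima lie
#' closer than `minSeparation` pixels. Ties on a flat two-pixel plateau keep
#' the pixel earlier in (column, row) order, so the result is deterministic.
#'
#' @param filtered 2-D numeric matrix.
#' @param threshold absolute intensity threshold (> 0); maxima must exceed it
#'   strictly.
#' @param minSeparation minimum candidate spacing in pixels.
#' @return data frame `row`, `col` (1-based pixel indices), `value`, ordered
#'   by (row, col); zero rows when nothing exceeds the threshold.
#' @export
findCandidates <- function(filtered, threshold, minSeparation = 5) {
  if (!is.matrix(filtered)) stop("filtered must be a matrix")
  stopifnotPositive(threshold = threshold, minSeparation = minSeparation)
  H <- nrow(filtered); W <- ncol(filtered)
  P <- matrix(-Inf, H + 2L, W + 2L)
  P[2:(H + 1), 2:(W + 1)] <- filtered
  ctr <- filtered
  ismax <- ctr > threshold
  for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- P[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    earlier <- dc < 0 || (dc == 0 && dr < 0)  # column-major predecessor
    ismax <- ismax & (if (earlier) ctr > nb else ctr >= nb)
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  val <- ctr[ismax]
  # suppress near-coincident maxima: brighter first, ties by (row, col)
  o <- order(-val, idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]; val <- val[o]
  keep <- logical(length(val))
  kr <- numeric(0); kc <- numeric(0)
  for (k in seq_along(val)) {
    if (length(kr) == 0 ||
        min((idx[k, 1] - kr)^2 + (idx[k, 2] - kc)^2) >= minSeparation^2) {
      keep[k] <- TRUE
      kr <- c(kr, idx[k, 1]); kc <- c(kc, idx[k, 2])
    }
  }
  out <- data.frame(row = idx[keep, 1], col = idx[keep, 2], value = val[keep])
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subpixel localization by radial symmetry
#'
#' Estimates the center of a bright spot as the point most consistent with
#' the local intensity gradient field: gradients are computed on the lattice
#' of pixel-corner midpoints, each midpoint defines a line through it along
#' its gradient direction (for a radially symmetric spot every such line
#' passes through the center), and the returned point minimizes the weighted
#' sum of squared distances to all lines. Weights are the squared gradient
#' magnitude divided by the midpoint's distance from the gradient-weighted
#' centroid, and the gradient field is smoothed with a 3x3 boxcar. This is
#' the standard radial-symmetry particle localizer, accurate to ~0.01 px on
#' clean spots at a fraction of the cost of Gaussian fitting.
#'
#' @param roi square intensity matrix with odd side length >= 5, centered on
#'   the candidate pixel.
#' @return `c(dx, dy)`: subpixel offset of the spot center from the patch
#'   center, in pixels (`dx` along columns, `dy` along rows).
#' @examples
#' spot <- exp(-(outer((-3:3 + 0.2)^2, (-3:3 - 0.3)^2, "+")) / (2 * 1.3^2))
#' localizeRadialSymmetry(spot)  # ~ (dx = +0.3, dy = -0.2)
#' @export
localizeRadialSymmetry <- function(roi) {
  if (!is.matrix(roi) || nrow(roi) != ncol(roi))
    stop("roi must be a square matrix")
  n <- nrow(roi)
  if (n < 5 || n %% 2 == 0) stop("roi side length must be odd and >= 5")
  # gradients on the (n-1) x (n-1) midpoint lattice; x = col, y = row
  a <- roi[1:(n - 1), 1:(n - 1)]; b <- roi[1:(n - 1), 2:n]
  d <- roi[2:n, 1:(n - 1)];       e <- roi[2:n, 2:n]
  gx <- 0.5 * (b - a + e - d)
  gy <- 0.5 * (d - a + e - b)
  sm <- function(g) {  # zero-padded 3x3 boxcar
    m <- nrow(g)
    gp <- matrix(0, m + 2, m + 2); gp[2:(m + 1), 2:(m + 1)] <- g
    (gp[1:m, 1:m] + gp[1:m, 2:(m + 1)] + gp[1:m, 3:(m + 2)] +
     gp[2:(m + 1), 1:m] + gp[2:(m + 1), 2:(m + 1)] + gp[2:(m + 1), 3:(m + 2)] +
     gp[3:(m + 2), 1:m] + gp[3:(m + 2), 2:(m + 1)] + gp[3:(m + 2), 3:(m + 2)]) / 9
  }
  gx <- sm(gx); gy <- sm(gy)
  g2 <- gx^2 + gy^2
  if (sum(g2) <= 0)
    stop(errorCondition("flat roi: radial-symmetry localization undefined",
                        class = "localizationUndefined"))
  m <- n - 1
  ctr <- (n + 1) / 2
  xm <- matrix(rep(seq_len(m) + 0.5, each = m), m, m)   # midpoint columns
  ym <- matrix(rep(seq_len(m) + 0.5, times = m), m, m)  # midpoint rows
  w0 <- g2 / sum(g2)
  xc0 <- sum(w0 * xm); yc0 <- sum(w0 * ym)
  dc <- sqrt((xm - xc0)^2 + (ym - yc0)^2)
  dc[dc < 1e-9] <- 1e-9
  w <- g2 / dc
  gg <- pmax(g2, 1e-300)
  vx2 <- gx^2 / gg; vy2 <- gy^2 / gg; vxy <- gx * gy / gg
  A11 <- sum(w * (1 - vx2)); A22 <- sum(w * (1 - vy2)); A12 <- -sum(w * vxy)
  b1 <- sum(w * ((1 - vx2) * xm - vxy * ym))
  b2 <- sum(w * ((1 - vy2) * ym - vxy * xm))
  det <- A11 * A22 - A12^2
  if (!is.finite(det) || abs(det) < 1e-12)
    stop(errorCondition("degenerate gradient field: localization undefined",
                        class = "localizationUndefined"))
  xc <- (A22 * b1 - A12 * b2) / det
  yc <- (A11 * b2 - A12 * b1) / det
  off <- c(dx = xc - ctr, dy = yc - ctr)
  if (any(abs(off) > n / 2))
    stop(errorCondition("localization outside roi: undefined",
                        class = "localizationUndefined"))
  off
}

#' Detect and localize spots in every frame of a movie
#'
#' Runs the full per-frame detection sequence — bandpass filter, intensity
#' threshold, radial-symmetry localization — and converts pixel positions to
#' micrometers using the stack's pixel size. Candidates too close to the
#' frame border for a full ROI are skipped; candidates whose localization is
#' undefined (flat ROI) are dropped with a warning.
#'
#' @param stack a [FrameStack-class].
#' @param sigmaNoise,sigmaObject bandpass scales in pixels, see
#'   [bandpassFilter()].
#' @param threshold `"auto"` (mean + `thresholdNsd` SD of each filtered
#'   frame) or an absolute intensity value.
#' @param thresholdNsd number of SDs above the mean for the auto threshold.
#' @param minSeparation minimum candidate spacing in pixels.
#' @param roiSize localization ROI side length in pixels (odd, >= 5).
#' @param invert invert intensities first (bright-field movies, where cells
#'   are dark objects on a light background).
#' @return data frame of detections: `frame`, `x`, `y` (micrometers),
#'   `intensity` (summed filtered ROI intensity), `row_px`, `col_px`
#'   (candidate pixel), sorted by (frame, x, y). Carries `pixelSize` and
#'   `frameInterval` attributes for downstream linking.
#' @examples
#' fs <- simulateMovie(widthPx = 48, heightPx = 48, nFrames = 4, nCells = 2,
#'                     motileFraction = 0, seed = 2)
#' head(detectStack(fs))
#' @export
detectStack <- function(stack, sigmaNoise = 1, sigmaObject = 4,
                        threshold = "auto", thresholdNsd = 4,
                        minSeparation = 5, roiSize = 7, invert = FALSE) {
  stopifnot(is(stack, "FrameStack"))
  if (roiSize < 5 || roiSize %% 2 == 0) stop("roiSize must be odd and >= 5")
  margin <- roiSize %/% 2
  px <- pixelSize(stack)
  nf <- nFrames(stack)
  H <- dim(stack@frames)[1]; W <- dim(stack@frames)[2]
  out <- vector("list", nf)
  nDropped <- 0L
  for (t in seq_len(nf)) {
    f <- stack@frames[, , t]
    if (invert) f <- max(f) - f
    filt <- bandpassFilter(f, sigmaNoise, sigmaObject)
    thr <- if (identical(threshold, "auto"))
      mean(filt) + thresholdNsd * stats::sd(filt) else threshold
    cand <- findCandidates(filt, thr, minSeparation)
    if (nrow(cand) == 0) next
    inb <- cand$row > margin & cand$row <= H - margin &
           cand$col > margin & cand$col <= W - margin
    cand <- cand[inb, , drop = FALSE]
    if (nrow(cand) == 0) next
    res <- matrix(NA_real_, nrow(cand), 6L)
    for (k in seq_len(nrow(cand))) {
      r <- cand$row[k]; cc <- cand$col[k]
      roi <- filt[(r - margin):(r + margin), (cc - margin):(cc + margin)]
      off <- tryCatch(localizeRadialSymmetry(roi),
                      localizationUndefined = function(e) NULL)
      if (is.null(off)) { nDropped <- nDropped + 1L; next }
      res[k, ] <- c(t, (cc + off[["dx"]] - 1) * px,
                    (r + off[["dy"]] - 1) * px, sum(roi), r, cc)
    }
    res <- res[!is.na(res[, 1]), , drop = FALSE]
    if (nrow(res)) out[[t]] <- res
  }
  if (nDropped > 0)
    warning(nDropped, " candidate(s) dropped: localization undefined")
  out <- out[!vapply(out, is.null, logical(1))]
  det <- if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3],
               intensity = m[, 4], row_px = as.integer(m[, 5]),
               col_px = as.integer(m[, 6]))
  } else
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               intensity = numeric(), row_px = integer(), col_px = integer())
  det <- det[order(det$frame, det$x, det$y), , drop = FALSE]
  rownames(det) <- NULL
  attr(det, "pixelSize") <- px
  attr(det, "frameInterval") <- frameInterval(stack)
  det
}
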