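#' Simulate a time-lapse movie of swimming and non-motile bacteria
#'
#' Generates a synthetic microscopy movie emulating bacteria imaged at the
#' bottom surface of a flask, together with the ground-truth trajectories of
#' every cell. Motile cells follow a run-and-tumble walk: they move at a
#' constant per-cell speed and resample their heading uniformly at Poisson
#' rate `tumbleRate`; non-motile cells jiggle by Brownian motion with
#' diffusion coefficient `diffusionCoeff`. Cells reflect off the field
#' boundaries so the cell count is conserved. Each cell is rendered in every
#' frame as an isotropic Gaussian spot of width `psfSigma` and integrated
#' intensity `spotIntensity`, on top of a constant `backgroundLevel` with
#' additive Gaussian noise of standard deviation `noiseSd` (optionally
#' Poisson shot noise instead).
#'
#' Exactly `round(nCells * motileFraction)` cells are motile, so the
#' realized composition equals the requested fraction: the ground truth is a
#' sharp oracle for the detection/tracking/classification pipeline rather
#' than a binomial draw around it. Motile speeds are drawn per cell from
#' `Normal(speedMean, speedSd)` truncated at zero.
#'
#' @param widthPx,heightPx frame size in pixels.
#' @param nFrames number of frames (>= 2).
#' @param frameInterval seconds per frame.
#' @param pixelSize micrometers per pixel.
#' @param nCells number of cells (0 gives a pure background movie).
#' @param motileFraction fraction of cells that are motile, in \[0, 1\].
#' @param speedMean,speedSd mean and SD of motile cell speeds (um/s).
#' @param tumbleRate direction-resampling rate for motile cells (events/s).
#' @param diffusionCoeff Brownian diffusion coefficient of non-motile cells
#'   (um^2/s).
#' @param psfSigma Gaussian spot width (pixels).
#' @param spotIntensity integrated intensity of one rendered spot (counts).
#' @param backgroundLevel constant background intensity (counts).
#' @param noiseSd additive Gaussian noise SD (counts); 0 for noiseless.
#' @param poissonNoise if `TRUE`, replace each pixel by a Poisson draw with
#'   that mean (shot noise) before adding Gaussian noise.
#' @param seed integer seed; identical seeds give bit-identical movies.
#' @return A [FrameStack-class] whose `groundTruth()` holds one row per cell
#'   per frame (`cell_id`, `frame`, `x_um`, `y_um`, `is_motile`,
#'   `true_speed_um_s`).
#' @examples
#' fs <- simulateMovie(widthPx = 64, heightPx = 64, nFrames = 10, nCells = 3,
#'                     seed = 1)
#' fs
#' @export
simulateMovie <- function(widthPx = 512, heightPx = 512, nFrames = 600,
                          frameInterval = 0.05, pixelSize = 0.325,
                          nCells = 60, motileFraction = 0.5,
                          speedMean = 5.6, speedSd = 0.5, tumbleRate = 1,
                          diffusionCoeff = 0.02, psfSigma = 1.3,
                          spotIntensity = 2000, backgroundLevel = 100,
                          noiseSd = 5, poissonNoise = FALSE, seed = NULL) {
  stopifnotPositive(widthPx = widthPx, heightPx = heightPx,
                    frameInterval = frameInterval, pixelSize = pixelSize,
                    psfSigma = psfSigma)
  if (nFrames < 2) stop("nFrames must be >= 2")
  if (nCells < 0) stop("nCells must be >= 0")
  if (motileFraction < 0 || motileFraction > 1)
    stop("motileFraction must lie in [0, 1]")
  if (motileFraction > 0 && nCells > 0 && speedMean <= 0)
    stop("speedMean must be > 0 when motile cells are requested")
  if (noiseSd < 0 || diffusionCoeff < 0 || tumbleRate < 0 || speedSd < 0)
    stop("noiseSd, diffusionCoeff, tumbleRate and speedSd must be >= 0")

  params <- list(widthPx = widthPx, heightPx = heightPx, nFrames = nFrames,
                 frameInterval = frameInterval, pixelSize = pixelSize,
                 nCells = nCells, motileFraction = motileFraction,
                 speedMean = speedMean, speedSd = speedSd,
                 tumbleRate = tumbleRate, diffusionCoeff = diffusionCoeff,
                 psfSigma = psfSigma, spotIntensity = spotIntensity,
                 backgroundLevel = backgroundLevel, noiseSd = noiseSd,
                 poissonNoise = poissonNoise, seed = seed)

  withSeed(seed, {
    gt <- simulateGroundTruth(params)
    frames <- renderMovie(gt, params)
    FrameStack(frames, pixelSize = pixelSize, frameInterval = frameInterval,
               groundTruth = gt, metadata = params)
  })
}

# Ground-truth positions (um) for all cells and frames; field spans
# [0, (n_px - 1) * pixelSize] per axis (pixel-center coordinates).
simulateGroundTruth <- function(p) {
  n <- p$nCells
  empty <- data.frame(cell_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      is_motile = logical(), true_speed_um_s = numeric())
  if (n == 0) return(empty)
  xmax <- (p$widthPx - 1) * p$pixelSize
  ymax <- (p$heightPx - 1) * p$pixelSize
  dt <- p$frameInterval
  nMot <- round(n * p$motileFraction)
  motile <- seq_len(n) <= nMot
  speed <- numeric(n)
  if (nMot > 0) {
    v <- stats::rnorm(nMot, p$speedMean, p$speedSd)
    bad <- which(v <= 0)
    while (length(bad)) {  # truncate speed distribution at zero
      v[bad] <- stats::rnorm(length(bad), p$speedMean, p$speedSd)
      bad <- bad[v[bad] <= 0]
    }
    speed[motile] <- v
  }
  x <- stats::runif(n, 0, xmax)
  y <- stats::runif(n, 0, ymax)
  ang <- stats::runif(n, 0, 2 * pi)
  ux <- cos(ang); uy <- sin(ang)
  pTumble <- 1 - exp(-p$tumbleRate * dt)
  sdStep <- sqrt(2 * p$diffusionCoeff * dt)

  X <- matrix(0, p$nFrames, n); Y <- matrix(0, p$nFrames, n)
  X[1, ] <- x; Y[1, ] <- y
  for (t in 2:p$nFrames) {
    if (nMot > 0) {
      tum <- motile & (stats::runif(n) < pTumble)
      if (any(tum)) {
        a <- stats::runif(sum(tum), 0, 2 * pi)
        ux[tum] <- cos(a); uy[tum] <- sin(a)
      }
    }
    dx <- dy <- numeric(n)
    dx[motile] <- speed[motile] * dt * ux[motile]
    dy[motile] <- speed[motile] * dt * uy[motile]
    if (any(!motile) && sdStep > 0) {
      dx[!motile] <- stats::rnorm(sum(!motile), 0, sdStep)
      dy[!motile] <- stats::rnorm(sum(!motile), 0, sdStep)
    }
    nx <- x + dx; ny <- y + dy
    # reflect at boundaries; swimming direction mirrors with the fold
    lo <- nx < 0; hi <- nx > xmax
    nx[lo] <- -nx[lo]; nx[hi] <- 2 * xmax - nx[hi]
    ux[lo | hi] <- -ux[lo | hi]
    lo <- ny < 0; hi <- ny > ymax
    ny[lo] <- -ny[lo]; ny[hi] <- 2 * ymax - ny[hi]
    uy[lo | hi] <- -uy[lo | hi]
    x <- nx; y <- ny
    X[t, ] <- x; Y[t, ] <- y
  }
  data.frame(
    cell_id = rep(seq_len(n), each = p$nFrames),
    frame = rep(seq_len(p$nFrames), times = n),
    x_um = as.vector(X), y_um = as.vector(Y),
    is_motile = rep(motile, each = p$nFrames),
    true_speed_um_s = rep(speed, each = p$nFrames)
  )
}

# Render ground truth into an intensity array (row, col, frame).
renderMovie <- function(gt, p) {
  H <- p$heightPx; W <- p$widthPx
  frames <- array(0, dim = c(H, W, p$nFrames))
  amp <- p$spotIntensity / (2 * pi * p$psfSigma^2)
  win <- ceiling(4 * p$psfSigma)
  s2 <- 2 * p$psfSigma^2
  byFrame <- if (nrow(gt) > 0) split(seq_len(nrow(gt)), gt$frame) else list()
  for (t in seq_len(p$nFrames)) {
    img <- matrix(p$backgroundLevel, H, W)
    idx <- byFrame[[as.character(t)]]
    for (k in idx) {
      colC <- gt$x_um[k] / p$pixelSize + 1
      rowC <- gt$y_um[k] / p$pixelSize + 1
      r0 <- max(1L, floor(rowC) - win); r1 <- min(H, ceiling(rowC) + win)
      c0 <- max(1L, floor(colC) - win); c1 <- min(W, ceiling(colC) + win)
      if (r0 > r1 || c0 > c1) next
      er <- exp(-((r0:r1) - rowC)^2 / s2)
      ec <- exp(-((c0:c1) - colC)^2 / s2)
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * (er %o% ec)
    }
    if (p$poissonNoise) img <- matrix(stats::rpois(H * W, img), H, W)
    if (p$noiseSd > 0) img <- img + stats::rnorm(H * W, 0, p$noiseSd)
    frames[, , t] <- pmax(img, 0)
  }
  frames
}
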