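# Independent oracles and small fixture builders used across test files.
# These re-derive expected values by brute force and stay independent of the
# implementation paths they check.

# Explicit-loop separable Gaussian blur with edge-renormalized truncated
# kernels: four nested loops, no matrix algebra.
bruteBlur <- function(img, sigma) {
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0; wsum <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        w <- k[di + r + 1] * k[dj + r + 1]
        acc <- acc + w * img[ii, jj]
        wsum <- wsum + w
      }
    }
    # separable edge renormalization: product of per-axis in-bounds masses
    wr <- sum(k[pmax(1 - i, -r):pmin(H - i, r) + r + 1])
    wc <- sum(k[pmax(1 - j, -r):pmin(W - j, r) + r + 1])
    out[i, j] <- acc / (wr * wc)
  }
  out
}

bruteBandpass <- function(img, s1, s2) {
  pmax(bruteBlur(img, s1) - bruteBlur(img, s2), 0)
}

# Analytic Gaussian spot sampled at pixel centers of an n x n patch, center
# offset (dx, dy) from the patch center (dx along columns, dy along rows).
renderSpot <- function(n, dx, dy, sigma, amp = 1, support = Inf) {
  ctr <- (n + 1) / 2
  cols <- matrix(rep(1:n, each = n), n, n)
  rows <- matrix(rep(1:n, times = n), n, n)
  d2 <- (cols - ctr - dx)^2 + (rows - ctr - dy)^2
  out <- amp * exp(-d2 / (2 * sigma^2))
  out[d2 > support^2] <- 0
  out
}

# Exhaustive minimum-distance assignment between two point sets under a
# distance gate: enumerates every injective partial matching, keeps maximum
# cardinality, then minimum total distance. Returns a 2-column matrix of
# (index in a, index in b) links.
oracleAssign <- function(ax, ay, bx, by, gate) {
  na <- length(ax); nb <- length(bx)
  d <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  best <- list(card = -1L, total = Inf, links = matrix(0L, 0, 2))
  rec <- function(i, usedB, links, total) {
    if (i > na) {
      card <- nrow(links)
      if (card > best$card ||
          (card == best$card && total < best$total - 1e-12)) {
        best <<- list(card = card, total = total, links = links)
      }
      return(invisible(NULL))
    }
    rec(i + 1L, usedB, links, total)  # leave a[i] unmatched
    for (j in seq_len(nb)) {
      if (!usedB[j] && d[i, j] <= gate^2) {
        u <- usedB; u[j] <- TRUE
        rec(i + 1L, u, rbind(links, c(i, j)), total + sqrt(d[i, j]))
      }
    }
  }
  rec(1L, rep(FALSE, nb), matrix(0L, 0, 2), 0)
  best$links
}

# Extract frame-pair links from a TrackSet as (prev row, cur row) index
# pairs into the detection table (matched on frame and coordinates).
extractLinks <- function(tracks, det) {
  p <- trackPoints(tracks)
  key <- function(f, x, y) paste(f, signif(x, 12), signif(y, 12))
  rowOf <- setNames(seq_len(nrow(det)), key(det$frame, det$x, det$y))
  p <- p[order(p$track_id, p$frame), ]
  links <- list()
  for (id in unique(p$track_id)) {
    q <- p[p$track_id == id, ]
    if (nrow(q) > 1) {
      for (k in 2:nrow(q)) {
        links[[length(links) + 1]] <- c(
          rowOf[[key(q$frame[k - 1], q$x[k - 1], q$y[k - 1])]],
          rowOf[[key(q$frame[k], q$x[k], q$y[k])]])
      }
    }
  }
  if (length(links)) do.call(rbind, links) else matrix(0L, 0, 2)
}

canonLinks <- function(m) {
  if (nrow(m) == 0) return(character(0))
  sort(paste(m[, 1], m[, 2]))
}

# Match detections to ground-truth positions frame by frame (nearest
# neighbor within a pixel radius); returns per-detection match distance in
# pixels (NA = unmatched) and per-cell-per-frame recall.
matchToTruth <- function(det, gt, radiusPx, pixelSize) {
  errs <- rep(NA_real_, nrow(det))
  hit <- logical(nrow(gt))
  for (f in unique(det$frame)) {
    di <- which(det$frame == f)
    gi <- which(gt$frame == f)
    if (!length(gi)) next
    for (k in di) {
      dd <- sqrt((det$x[k] - gt$x_um[gi])^2 + (det$y[k] - gt$y_um[gi])^2) /
        pixelSize
      j <- which.min(dd)
      if (dd[j] <= radiusPx) {
        errs[k] <- dd[j]
        hit[gi[j]] <- TRUE
      }
    }
  }
  list(errPx = errs, recall = mean(hit))
}

# Closed-form Wilson score interval (no continuity correction).
wilsonCI <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

# Small high-SNR movie used by several end-to-end tests.
quickMovie <- function(seed, nCells = 20, motileFraction = 0.6,
                       speedMean = 8.2, speedSd = 1.2, nFrames = 60,
                       sizePx = 128, noiseSd = 5) {
  simulateMovie(widthPx = sizePx, heightPx = sizePx, nFrames = nFrames,
                nCells = nCells, motileFraction = motileFraction,
                speedMean = speedMean, speedSd = speedSd,
                noiseSd = noiseSd, seed = seed)
}
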