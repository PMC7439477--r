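# Synthetic-data generators: movies with ground truth, competition count
# tables, serial-passage trajectories.

test_that("movie with no cells is pure background plus noise", {
  fs <- simulateMovie(widthPx = 32, heightPx = 32, nFrames = 3, nCells = 0,
                      backgroundLevel = 50, noiseSd = 2, seed = 1)
  expect_equal(nrow(groundTruth(fs)), 0)
  expect_equal(dim(fs@frames), c(32, 32, 3))
  expect_equal(mean(fs@frames), 50, tolerance = 0.05)
  # no spot structure: everything within a few noise SDs of background
  expect_lt(max(abs(fs@frames - 50)), 6 * 2)
})

test_that("static noiseless cell renders identically in every frame", {
  fs <- simulateMovie(widthPx = 32, heightPx = 32, nFrames = 5, nCells = 1,
                      motileFraction = 0, diffusionCoeff = 0, noiseSd = 0,
                      seed = 7)
  f1 <- getFrame(fs, 1)
  for (i in 2:5) expect_identical(getFrame(fs, i), f1)
  am <- which(f1 == max(f1), arr.ind = TRUE)
  for (i in 2:5) {
    fi <- getFrame(fs, i)
    expect_identical(which(fi == max(fi), arr.ind = TRUE), am)
  }
})

test_that("motile ground-truth displacements equal speed x interval", {
  fs <- simulateMovie(widthPx = 256, heightPx = 256, nFrames = 12,
                      nCells = 10, motileFraction = 1, speedMean = 5,
                      speedSd = 0, tumbleRate = 0, frameInterval = 0.05,
                      noiseSd = 0, seed = 3)
  gt <- groundTruth(fs)
  step <- 5 * 0.05
  xmax <- (256 - 1) * fs@pixelSize
  nChecked <- 0
  for (id in unique(gt$cell_id)) {
    g <- gt[gt$cell_id == id, ]
    g <- g[order(g$frame), ]
    d <- sqrt(diff(g$x_um)^2 + diff(g$y_um)^2)
    # reflection folds shorten a step; check steps away from boundaries
    awayFrom <- function(v) v > step & v < xmax - step
    free <- awayFrom(g$x_um[-1]) & awayFrom(g$x_um[-nrow(g)]) &
            awayFrom(g$y_um[-1]) & awayFrom(g$y_um[-nrow(g)])
    expect_equal(d[free], rep(step, sum(free)), tolerance = 1e-9)
    nChecked <- nChecked + sum(free)
  }
  expect_gt(nChecked, 50)
})

test_that("ground truth has one position per cell per frame", {
  fs <- quickMovie(seed = 5, nCells = 7, nFrames = 9)
  gt <- groundTruth(fs)
  expect_equal(nrow(gt), 7 * 9)
  expect_equal(nrow(unique(gt[, c("cell_id", "frame")])), 7 * 9)
  expect_true(all(gt$x_um >= 0 & gt$x_um <= 128 * pixelSize(fs)))
})

test_that("identical seed gives bit-identical movies and tables", {
  a <- simulateMovie(widthPx = 48, heightPx = 48, nFrames = 6, nCells = 5,
                     seed = 11)
  b <- simulateMovie(widthPx = 48, heightPx = 48, nFrames = 6, nCells = 5,
                     seed = 11)
  expect_identical(a@frames, b@frames)
  expect_identical(groundTruth(a), groundTruth(b))
  expect_identical(simulateCompetition(seed = 4), simulateCompetition(seed = 4))
  expect_identical(simulatePassages(seed = 4), simulatePassages(seed = 4))
})

test_that("rendered spot intensity matches the analytic Gaussian integral", {
  # single interior static cell on a noiseless frame
  fs <- simulateMovie(widthPx = 64, heightPx = 64, nFrames = 2, nCells = 1,
                      motileFraction = 0, diffusionCoeff = 0, noiseSd = 0,
                      spotIntensity = 2000, backgroundLevel = 10, seed = 21)
  gt <- groundTruth(fs)
  # fixture validity: the spot must sit well inside the frame
  margin <- 8 * pixelSize(fs)
  xmax <- (64 - 1) * pixelSize(fs)
  expect_true(all(gt$x_um > margin & gt$x_um < xmax - margin &
                  gt$y_um > margin & gt$y_um < xmax - margin))
  integrated <- sum(getFrame(fs, 1) - 10)
  expect_equal(integrated, 2000, tolerance = 0.01)
})

test_that("movie parameter validation rejects bad inputs", {
  expect_error(simulateMovie(motileFraction = 1.2), "motileFraction")
  expect_error(simulateMovie(widthPx = 0), "widthPx")
  expect_error(simulateMovie(nFrames = 1), "nFrames")
  expect_error(simulateMovie(motileFraction = 0.5, speedMean = 0), "speedMean")
})

test_that("neutral noiseless competition gives CI exactly 1", {
  tbl <- simulateCompetition(trueLogCI = 0, flaskSd = 0, gutSd = 0,
                             nFlasks = 2, gutsPerFlask = 4,
                             countingNoise = FALSE, seed = 1)
  ci <- competitiveIndex(tbl)
  expect_equal(ci$ci, rep(1, 8), tolerance = 1e-12)
})

test_that("deterministic log-CI shift appears exactly in noiseless CIs", {
  tbl <- simulateCompetition(trueLogCI = log(4), flaskSd = 0, gutSd = 0,
                             nFlasks = 2, gutsPerFlask = 3,
                             countingNoise = FALSE, seed = 1)
  ci <- competitiveIndex(tbl)
  expect_equal(ci$ci, rep(4, 6), tolerance = 1e-12)
})

test_that("flask random effect has the requested variance", {
  tbl <- simulateCompetition(trueLogCI = 0, flaskSd = 0.5, gutSd = 0,
                             nFlasks = 1000, gutsPerFlask = 2,
                             countingNoise = FALSE, seed = 9)
  ci <- competitiveIndex(tbl)
  flaskMeanLog <- tapply(log(ci$ci), ci$flask_id, mean)
  expect_equal(var(as.numeric(flaskMeanLog)), 0.25, tolerance = 0.2)
})

test_that("neutral passage frequencies form a martingale at the founder", {
  finals <- vapply(1:200, function(s)
    simulatePassages(s = 0, bottleneckSize = 1000,
                     seed = s)$freq_dtomato[21], numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 3 * se + 1e-12)
})

test_that("drift vanishes for very large bottlenecks", {
  tr <- simulatePassages(s = 0, bottleneckSize = 1e6, seed = 2)
  expect_true(all(abs(tr$freq_dtomato - 0.5) < 0.01))
  expect_equal(tr$freq_dtomato + tr$freq_gfp, rep(1, 21))
  expect_true(all(tr$freq_dtomato >= 0 & tr$freq_dtomato <= 1))
})

test_that("selection follows the logistic closed form at large bottlenecks", {
  s <- 0.5
  tr <- simulatePassages(nPassages = 10, s = s, tMut = 1,
                         mutBackground = "dTomato", bottleneckSize = 1e6,
                         seed = 13)
  odds0 <- 0.5 / 0.5
  expected <- vapply(1:10, function(t) {
    o <- odds0 * (1 + s)^t
    o / (1 + o)
  }, numeric(1))
  expect_equal(tr$freq_dtomato[-1], expected, tolerance = 0.01)
  expect_true(all(diff(tr$freq_dtomato) >= -0.005))
})

test_that("passage parameter validation rejects bad inputs", {
  expect_error(simulatePassages(founderFreq = 0), "founderFreq")
  expect_error(simulatePassages(tMut = 25), "tMut")
  expect_error(simulatePassages(bottleneckSize = 0), "bottleneckSize")
})
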