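#' Simulate a gut-colonization competition experiment
#'
#' Generates a CFU count table with the two-level noise structure of a
#' flask-replicated competition assay: each flask draws a random effect on
#' the log competitive index (`Normal(0, flaskSd^2)`), each dissected gut
#' within a flask draws its own log CI around the flask value
#' (`Normal(trueLogCI + flask effect, gutSd^2)`), and plate counting is
#' layered on top — the total gut load is log-normal, split binomially
#' between the competitors at the ratio implied by the gut's CI, and the
#' per-flask inoculum triplicates are Poisson counts around a 1:1 ratio.
#' With `countingNoise = FALSE` counts are exact expectations (real-valued),
#' so with `flaskSd = gutSd = 0` every per-gut CI equals `exp(trueLogCI)`
#' exactly.
#'
#' @param trueLogCI true competitive index on the natural-log scale
#'   (0 = neutral).
#' @param nFlasks,gutsPerFlask replication structure.
#' @param flaskSd,gutSd SDs of the flask random effect and the per-gut
#'   residual, on the natural-log CI scale.
#' @param inoculumDensity inoculation density (CFU/ml).
#' @param plateVolume plated volume (ml) for the inoculum triplicates.
#' @param plateDilution fold dilution of the plated inoculum samples.
#' @param totalLoadMeanLog,totalLoadSdLog log-normal parameters of the total
#'   per-gut CFU count.
#' @param countingNoise draw integer plate counts (`TRUE`) or record exact
#'   expected counts (`FALSE`).
#' @param seed integer seed; identical seeds give identical tables.
#' @return Combined count table (see [competitiveIndex()] for the layout):
#'   one row per gut plus three inoculum rows per flask. A warning is issued
#'   (and the rows flagged in the `low_inoculum` column) if the expected
#'   inoculum plate count falls below one colony.
#' @export
simulateCompetition <- function(trueLogCI = 0, nFlasks = 6, gutsPerFlask = 20,
                                flaskSd = 0.1, gutSd = 0.3,
                                inoculumDensity = 1000, plateVolume = 0.1,
                                plateDilution = 1,
                                totalLoadMeanLog = log(2000),
                                totalLoadSdLog = 0.5,
                                countingNoise = TRUE, seed = NULL) {
  if (nFlasks < 1 || gutsPerFlask < 1)
    stop("nFlasks and gutsPerFlask must be >= 1")
  if (flaskSd < 0 || gutSd < 0) stop("flaskSd and gutSd must be >= 0")
  stopifnotPositive(inoculumDensity = inoculumDensity,
                    plateVolume = plateVolume, plateDilution = plateDilution)
  withSeed(seed, {
    flaskIds <- sprintf("F%d", seq_len(nFlasks))
    flaskEff <- stats::rnorm(nFlasks, 0, flaskSd)
    gut <- do.call(rbind, lapply(seq_len(nFlasks), function(i) {
      logci <- stats::rnorm(gutsPerFlask, trueLogCI + flaskEff[i], gutSd)
      p1 <- 1 / (1 + exp(-logci))  # comp1 share at a 1:1 inoculum
      if (countingNoise) {
        tot <- round(stats::rlnorm(gutsPerFlask, totalLoadMeanLog,
                                   totalLoadSdLog))
        tot <- pmax(tot, 1)
        c1 <- stats::rbinom(gutsPerFlask, tot, p1)
      } else {
        tot <- exp(totalLoadMeanLog)
        c1 <- tot * p1
      }
      data.frame(flask_id = flaskIds[i], gut_id = seq_len(gutsPerFlask),
                 count_comp1 = c1, count_comp2 = tot - c1,
                 inoc_rep = NA_integer_,
                 inoc_count_comp1 = NA_real_, inoc_count_comp2 = NA_real_,
                 dilution = 1)
    }))
    lambda <- inoculumDensity * plateVolume / (2 * plateDilution)
    lowInoc <- lambda < 1
    if (lowInoc)
      warning("expected inoculum plate count below 1 colony (",
              signif(lambda, 3), "); inoculation ratios will be unreliable")
    inoc <- do.call(rbind, lapply(seq_len(nFlasks), function(i) {
      if (countingNoise) {
        i1 <- stats::rpois(3, lambda); i2 <- stats::rpois(3, lambda)
      } else {
        i1 <- i2 <- rep(lambda, 3)
      }
      data.frame(flask_id = flaskIds[i], gut_id = NA_integer_,
                 count_comp1 = NA_real_, count_comp2 = NA_real_,
                 inoc_rep = 1:3,
                 inoc_count_comp1 = i1, inoc_count_comp2 = i2,
                 dilution = plateDilution)
    }))
    out <- rbind(gut, inoc)
    out$low_inoculum <- lowInoc
    rownames(out) <- NULL
    attr(out, "params") <- list(trueLogCI = trueLogCI, nFlasks = nFlasks,
                                gutsPerFlask = gutsPerFlask,
                                flaskSd = flaskSd, gutSd = gutSd,
                                seed = seed)
    out
  })
}
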