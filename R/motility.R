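# Per-track speed statistics: motile classification at an operational speed
# cutoff, Wilson confidence intervals for motile fractions, per-flask
# relative-speed ratios tested against 1.

#' Mean per-step speed of a single track
#'
#' Speed is the mean over consecutive frame pairs of Euclidean displacement
#' divided by the frame interval — the mean instantaneous speed along the
#' path, not net displacement over duration (which underestimates the speed
#' of run-and-tumble swimmers).
#'
#' @param points data frame or matrix with columns `x`, `y` in micrometers,
#'   one row per consecutive frame.
#' @param frameInterval seconds per frame.
#' @return Speed in micrometers/second.
#' @examples
#' trackSpeed(data.frame(x = c(0, 0.25, 0.5), y = 0), frameInterval = 0.05)
#' @export
trackSpeed <- function(points, frameInterval) {
  stopifnotPositive(frameInterval = frameInterval)
  points <- as.data.frame(points)
  if (nrow(points) < 2)
    stop("speed undefined for a track with fewer than 2 points")
  mean(sqrt(diff(points$x)^2 + diff(points$y)^2)) / frameInterval
}

#' Build per-track speed records for one movie
#'
#' @param tracks a [TrackSet-class] (normally after [filterTracks()]).
#' @param flaskId,strain labels attached to every record (one movie images
#'   one tagged population in one flask).
#' @param cutoff motile classification cutoff in micrometers/second.
#' @return data frame `track_id`, `flask_id`, `strain`, `mean_speed`,
#'   `is_motile` (`mean_speed > cutoff`). Single-point tracks (speed
#'   undefined) are excluded.
#' @export
speedRecords <- function(tracks, flaskId, strain, cutoff = 2) {
  stopifnot(is(tracks, "TrackSet"))
  sp <- trackSpeeds(tracks)
  sp <- sp[!is.na(sp)]
  data.frame(
    track_id = as.integer(names(sp)),
    flask_id = rep(flaskId, length(sp)),
    strain = rep(strain, length(sp)),
    mean_speed = as.numeric(sp),
    is_motile = as.numeric(sp) > cutoff,
    row.names = NULL
  )
}

#' Motile-fraction summary per flask and strain
#'
#' Classifies each track as motile when its mean speed exceeds `cutoff`
#' (the operational definition; no correction is applied for the
#' localization noise floor, which [noiseFloorSpeed()] reports separately)
#' and summarizes each (flask, strain) group: motile fraction with a Wilson
#' 95% confidence interval, and the mean speed of the motile tracks.
#'
#' @param records data frame from [speedRecords()] (rows from several movies
#'   may be concatenated); columns `flask_id`, `strain`, `mean_speed`.
#' @param cutoff motile cutoff in micrometers/second (default 2).
#' @param conf confidence level for the Wilson interval.
#' @return data frame with one row per (flask_id, strain): `n_tracks`,
#'   `n_motile`, `motile_fraction`, `ci_lo`, `ci_hi`, `mean_speed_motile`
#'   (`NA` when no track is motile).
#' @export
classifyMotile <- function(records, cutoff = 2, conf = 0.95) {
  if (nrow(records) == 0) stop("no speed records: empty group")
  key <- interaction(records$flask_id, records$strain, drop = TRUE)
  res <- lapply(split(records, key), function(g) {
    n <- nrow(g)
    x <- sum(g$mean_speed > cutoff)
    # (warning about the chi-squared test statistic is irrelevant here:
    # only the Wilson interval is used)
    ci <- suppressWarnings(
      stats::prop.test(x, n, correct = FALSE, conf.level = conf)$conf.int)
    data.frame(
      flask_id = g$flask_id[1], strain = g$strain[1],
      n_tracks = n, n_motile = x, motile_fraction = x / n,
      ci_lo = ci[1], ci_hi = ci[2],
      mean_speed_motile = if (x > 0) mean(g$mean_speed[g$mean_speed > cutoff])
                          else NA_real_
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$strain, out$flask_id), , drop = FALSE]
}

#' Speed histogram
#'
#' Counts of track speeds in right-open bins of width `binWidth` from zero
#' upward, as used to compare a strain's speed distribution against the
#' ancestor with observations aggregated across flasks.
#'
#' @param speeds numeric vector of speeds (micrometers/second).
#' @param binWidth bin width in micrometers/second.
#' @param density normalize counts to a probability density.
#' @return data frame `bin_lo`, `bin_hi`, `count` (and `density` if
#'   requested); zero rows for empty input.
#' @export
speedHistogram <- function(speeds, binWidth = 1, density = FALSE) {
  stopifnotPositive(binWidth = binWidth)
  if (length(speeds) == 0)
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer()))
  if (any(speeds < 0)) stop("speeds must be non-negative")
  breaks <- seq(0, (floor(max(speeds) / binWidth) + 1) * binWidth, binWidth)
  h <- graphics::hist(speeds, breaks = breaks, right = FALSE, plot = FALSE)
  out <- data.frame(bin_lo = h$breaks[-length(h$breaks)],
                    bin_hi = h$breaks[-1], count = h$counts)
  if (density) out$density <- out$count / (sum(out$count) * binWidth)
  out
}

#' One-tailed test of per-flask relative speed against 1
#'
#' Each flask contributes one ratio: mean mutant swim speed divided by mean
#' ancestor swim speed in that flask. The ratios are tested against the null
#' value 1 with a one-sample, one-tailed (greater) t test — the null
#' expectation being that the mutant swims no faster than the ancestor.
#'
#' @param ratios either a numeric vector of per-flask ratios, or a data
#'   frame with columns `mutant_mean` and `ancestor_mean` (one row per
#'   flask) from which ratios are computed.
#' @return list with class `"relativeSpeedTest"`: `ratios`, `estimate`
#'   (mean ratio), `t`, `df`, `p.value` (one-tailed), `degenerate` (`TRUE`
#'   when the ratios have zero variance, in which case the t statistic is
#'   infinite and the p value is reported as a bound).
#' @export
relativeSpeedTest <- function(ratios) {
  if (is.data.frame(ratios)) {
    if (!all(c("mutant_mean", "ancestor_mean") %in% names(ratios)))
      stop("data frame input needs columns mutant_mean and ancestor_mean")
    ratios <- ratios$mutant_mean / ratios$ancestor_mean
  }
  ratios <- as.numeric(ratios)
  if (length(ratios) < 2)
    stop("insufficient replication: at least 2 flasks required")
  if (any(ratios <= 0)) stop("speed ratios must be positive")
  n <- length(ratios)
  if (stats::sd(ratios) == 0) {
    m <- mean(ratios)
    res <- list(ratios = ratios, estimate = m,
                t = if (m > 1) Inf else if (m < 1) -Inf else 0,
                df = n - 1,
                p.value = if (m > 1) 1e-12 else if (m < 1) 1 else 0.5,
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(ratios, mu = 1, alternative = "greater")
    res <- list(ratios = ratios, estimate = unname(tt$estimate),
                t = unname(tt$statistic), df = unname(tt$parameter),
                p.value = tt$p.value, degenerate = FALSE)
  }
  class(res) <- "relativeSpeedTest"
  res
}

#' @export
print.relativeSpeedTest <- function(x, ...) {
  cat("One-sample one-tailed t test of per-flask speed ratios vs 1\n")
  cat("  flasks:", length(x$ratios), " mean ratio:",
      format(x$estimate, digits = 4), "\n")
  cat("  t =", format(x$t, digits = 4), " df =", x$df,
      " p =", format.pval(x$p.value, digits = 4),
      if (x$degenerate) " (zero-variance ratios; p is a bound)" else "", "\n")
  invisible(x)
}

#' Estimated apparent-speed noise floor
#'
#' A perfectly stationary object acquires an apparent speed of roughly
#' `sqrt(2) * sigma_loc / frameInterval` from localization error alone
#' (actually `sqrt(pi) * sigma_loc / frameInterval` for the mean step of an
#' isotropic Gaussian error; both are reported). Compare this floor with the
#' motile cutoff when interpreting motile fractions: the operational cutoff
#' is applied to raw speeds with no noise correction.
#'
#' @param sigmaLoc per-coordinate localization error SD in micrometers.
#' @param frameInterval seconds per frame.
#' @return Named vector with the RMS (`rms`) and mean (`mean`) apparent
#'   step speed of a static object, in micrometers/second.
#' @export
noiseFloorSpeed <- function(sigmaLoc, frameInterval) {
  stopifnotPositive(frameInterval = frameInterval)
  c(rms = sqrt(2) * sigmaLoc / frameInterval,
    mean = sqrt(pi) * sigmaLoc / frameInterval)
}
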