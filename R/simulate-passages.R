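#' Simulate serial passage of a two-tag population through a host bottleneck
#'
#' Emulates the design in which six replicate populations founded as a 1:1
#' mix of gfp- and dTomato-tagged clones are passaged through larval guts:
#' each passage consists of deterministic within-passage growth followed by
#' a multinomial bottleneck of `bottleneckSize` cells at transfer. Growth
#' multiplies each tag lineage by `growthFactor`, and by
#' `growthFactor * (1 + s)` for the lineage carrying a beneficial mutation —
#' modeled as arising in the `mutBackground` tag at passage `tMut` and
#' sweeping with its background, so the tag's frequency tracks the mutant's.
#' Stochasticity acts only at the bottleneck, isolating drift at the
#' transfer step. With `s = 0` the tag frequency is a martingale at the
#' founding frequency; under selection, in the large-bottleneck limit the
#' tag odds grow geometrically:
#' `odds_t = odds_0 * (1 + s)^(t - tMut + 1)` for passages `t >= tMut`.
#'
#' @param nPassages number of transfers (default 20).
#' @param founderFreq founding dTomato frequency, in (0, 1) (default 0.5).
#' @param bottleneckSize cells sampled at each transfer (>= 1).
#' @param growthFactor fold expansion per passage (cancels from frequencies;
#'   kept for interface completeness).
#' @param s selection coefficient of the beneficial mutation (0 = neutral).
#' @param tMut passage at which the mutation arises (1..`nPassages`), or
#'   `NA` for no mutation.
#' @param mutBackground which tag carries the mutation.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return data frame with one row per passage (passage 0 is the founding
#'   population): `passage`, `count_dtomato`, `count_gfp` (post-transfer
#'   bottleneck counts), `freq_dtomato`, `freq_gfp`. If one tag drifts to
#'   extinction the trajectory continues at frequency 0/1.
#' @examples
#' simulatePassages(nPassages = 5, bottleneckSize = 100, seed = 1)
#' @export
simulatePassages <- function(nPassages = 20, founderFreq = 0.5,
                             bottleneckSize = 10000, growthFactor = 100,
                             s = 0, tMut = NA_integer_,
                             mutBackground = c("dTomato", "gfp"),
                             seed = NULL) {
  mutBackground <- match.arg(mutBackground)
  if (nPassages < 1) stop("nPassages must be >= 1")
  if (bottleneckSize < 1) stop("bottleneckSize must be >= 1")
  if (founderFreq <= 0 || founderFreq >= 1)
    stop("founderFreq must lie strictly between 0 and 1")
  stopifnotPositive(growthFactor = growthFactor)
  if (s < -1) stop("s must be > -1")
  if (!is.na(tMut) && (tMut < 1 || tMut > nPassages))
    stop("tMut must lie in [1, nPassages] (or NA for no mutation)")
  withSeed(seed, {
    nd <- round(founderFreq * bottleneckSize)
    ng <- bottleneckSize - nd
    out <- data.frame(passage = 0:nPassages,
                      count_dtomato = c(nd, integer(nPassages)),
                      count_gfp = c(ng, integer(nPassages)))
    for (t in seq_len(nPassages)) {
      selDt <- !is.na(tMut) && t >= tMut && mutBackground == "dTomato"
      selGfp <- !is.na(tMut) && t >= tMut && mutBackground == "gfp"
      wd <- nd * growthFactor * (1 + if (selDt) s else 0)
      wg <- ng * growthFactor * (1 + if (selGfp) s else 0)
      p <- if (wd + wg > 0) wd / (wd + wg) else 0
      nd <- stats::rbinom(1, bottleneckSize, p)
      ng <- bottleneckSize - nd
      out$count_dtomato[t + 1] <- nd
      out$count_gfp[t + 1] <- ng
    }
    out$freq_dtomato <- out$count_dtomato / bottleneckSize
    out$freq_gfp <- out$count_gfp / bottleneckSize
    attr(out, "params") <- list(nPassages = nPassages,
                                founderFreq = founderFreq,
                                bottleneckSize = bottleneckSize,
                                growthFactor = growthFactor, s = s,
                                tMut = tMut, mutBackground = mutBackground,
                                seed = seed)
    out
  })
}
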