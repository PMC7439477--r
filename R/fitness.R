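# Competitive-index fitness analysis from CFU count tables, flask-aware
# Dunnett comparisons against a control, and serial-passage tag-frequency
# summaries.

#' Per-gut competitive indices from a CFU count table
#'
#' The competitive index of a gut is the ratio of competitor 1 to
#' competitor 2 found in that gut divided by the mean inoculation ratio of
#' the flask it came from, where the mean inoculation ratio is the mean of
#' the per-triplicate ratios (not the ratio of summed counts). A single
#' zero gut count is replaced by `pseudocount` colonies at the plated
#' dilution (continuity correction) and the gut flagged `censored`; a gut
#' with both counts zero has an undefined index (`NA`, with a warning).
#'
#' @param tbl combined count table in the layout written by
#'   [simulateCompetition()]: gut rows carry `flask_id`, `gut_id`,
#'   `count_comp1`, `count_comp2` (and `inoc_rep = NA`); inoculum rows carry
#'   `flask_id`, `inoc_rep` (1..3), `inoc_count_comp1`, `inoc_count_comp2`.
#' @param pseudocount colonies substituted for a single zero count
#'   (default 0.5).
#' @return data frame `flask_id`, `gut_id`, `ci`, `log10_ci`, `censored`.
#' @examples
#' tbl <- simulateCompetition(nFlasks = 2, gutsPerFlask = 3, seed = 1)
#' competitiveIndex(tbl)
#' @export
competitiveIndex <- function(tbl, pseudocount = 0.5) {
  need <- c("flask_id", "gut_id", "count_comp1", "count_comp2",
            "inoc_rep", "inoc_count_comp1", "inoc_count_comp2")
  if (!all(need %in% names(tbl)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  inoc <- tbl[!is.na(tbl$inoc_rep), , drop = FALSE]
  guts <- tbl[is.na(tbl$inoc_rep), , drop = FALSE]
  if (nrow(inoc) == 0) stop("no inoculum rows in count table")
  inocRatio <- vapply(split(inoc, inoc$flask_id), function(g) {
    ok <- g$inoc_count_comp1 > 0 & g$inoc_count_comp2 > 0
    if (!any(ok))
      stop("all inoculum triplicates degenerate (zero counts) in flask ",
           g$flask_id[1])
    if (!all(ok))
      warning("degenerate inoculum triplicate(s) dropped in flask ",
              g$flask_id[1])
    mean(g$inoc_count_comp1[ok] / g$inoc_count_comp2[ok])
  }, numeric(1))
  c1 <- guts$count_comp1
  c2 <- guts$count_comp2
  bothZero <- c1 == 0 & c2 == 0
  if (any(bothZero))
    warning(sum(bothZero), " gut(s) with both counts zero: CI undefined")
  censored <- (c1 == 0 | c2 == 0) & !bothZero
  c1[c1 == 0] <- pseudocount
  c2[c2 == 0] <- pseudocount
  ci <- (c1 / c2) / inocRatio[as.character(guts$flask_id)]
  ci[bothZero] <- NA_real_
  censored[bothZero] <- NA
  out <- data.frame(flask_id = guts$flask_id, gut_id = guts$gut_id,
                    ci = unname(ci), log10_ci = unname(log10(ci)),
                    censored = censored)
  rownames(out) <- NULL
  out
}

#' Dunnett-style comparison of group fitness against a control
#'
#' Two-stage analysis respecting the flask grouping: stage 1 aggregates
#' log10 competitive indices to per-flask means, absorbing the flask random
#' effect so flasks (not guts) are the units of replication; stage 2 runs
#' Dunnett's many-to-one comparison of each group's flask means against the
#' control group's, with single-step multivariate-t adjustment and pooled
#' variance (via \pkg{multcomp}). With balanced flasks this matches the
#' contrast structure of a mixed model with a flask random effect.
#'
#' @param cis data frame from [competitiveIndex()] with an added `group`
#'   column (strain/treatment label).
#' @param control label of the control group (e.g. the ancestor-vs-ancestor
#'   competition).
#' @param alternative direction of the alternative, passed to the contrast
#'   (default two-sided, the usual display with significance stars).
#' @return data frame with one row per non-control group: `group`,
#'   `n_flasks`, `estimate` (difference in mean log10 CI vs control), `se`,
#'   `t_value`, `p_adj` (single-step adjusted), `stars` (`*`, `**`, `***` at
#'   0.05, 0.01, 0.001).
#' @export
dunnettVsControl <- function(cis, control,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!"group" %in% names(cis)) stop("cis must have a 'group' column")
  if (!control %in% cis$group)
    stop("control group '", control, "' not present in the data")
  cis <- cis[!is.na(cis$log10_ci), , drop = FALSE]
  fm <- stats::aggregate(log10_ci ~ group + flask_id, data = cis, FUN = mean)
  nf <- table(fm$group)
  few <- names(nf)[nf < 2]
  if (control %in% few)
    stop("control group has fewer than 2 flasks")
  if (length(few)) {
    warning("group(s) with a single flask excluded: ",
            paste(few, collapse = ", "))
    fm <- fm[!fm$group %in% few, , drop = FALSE]
  }
  fm$group <- stats::relevel(factor(fm$group), ref = control)
  fit <- stats::lm(log10_ci ~ group, data = fm)
  scaleY <- max(abs(fm$log10_ci), 1)
  if (suppressWarnings(summary(fit)$sigma) < 1e-10 * scaleY) {
    # degenerate zero-variance inputs: identical flask means carry no
    # evidence against equality; a non-zero difference with zero residual
    # variance is infinitely significant
    co <- stats::coef(fit)[-1]
    co[abs(co) < 1e-10 * scaleY] <- 0
    grp <- sub("^group", "", names(co))
    warning("zero residual variance across flask means; ",
            "p-values are boundary values")
    p <- ifelse(co == 0, 1, 0)
    return(data.frame(group = grp, n_flasks = as.integer(nf[grp]),
                      estimate = as.numeric(co), se = 0,
                      t_value = ifelse(co == 0, 0, sign(co) * Inf),
                      p_adj = p,
                      stars = ifelse(p < 0.001, "***", ""),
                      row.names = NULL))
  }
  glh <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"),
                        alternative = alternative)
  sm <- summary(glh)
  grp <- sub(" - .*$", "", names(sm$test$coefficients))
  p <- as.numeric(sm$test$pvalues)
  out <- data.frame(
    group = grp,
    n_flasks = as.integer(nf[grp]),
    estimate = as.numeric(sm$test$coefficients),
    se = as.numeric(sm$test$sigma),
    t_value = as.numeric(sm$test$tstat),
    p_adj = p,
    stars = ifelse(p < 0.001, "***",
            ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  )
  rownames(out) <- NULL
  out
}

#' Competitive index of a rich-medium (in vitro) competition
#'
#' For flask competitions read at two time points rather than from dissected
#' guts: CI is the mean final ratio of competitor 1 to competitor 2 divided
#' by the mean inoculation ratio, each a mean of per-triplicate ratios with
#' the same pseudocount rule as [competitiveIndex()].
#'
#' @param initial,final data frames with columns `count_comp1`,
#'   `count_comp2`, one row per triplicate plate.
#' @param pseudocount colonies substituted for a single zero count.
#' @return list: `ci`, `log10_ci`, `initial_ratio`, `final_ratio`.
#' @export
richMediumCI <- function(initial, final, pseudocount = 0.5) {
  meanRatio <- function(d, what) {
    if (nrow(d) == 0) stop("no ", what, " triplicates")
    c1 <- d$count_comp1; c2 <- d$count_comp2
    if (any(c1 == 0 & c2 == 0)) stop(what, " triplicate with both counts zero")
    c1[c1 == 0] <- pseudocount
    c2[c2 == 0] <- pseudocount
    mean(c1 / c2)
  }
  r0 <- meanRatio(initial, "initial")
  r1 <- meanRatio(final, "final")
  list(ci = r1 / r0, log10_ci = log10(r1 / r0),
       initial_ratio = r0, final_ratio = r1)
}

#' Summarize a serial-passage tag-count trajectory and flag sweeps
#'
#' Converts per-passage counts of the two fluorescent tags to frequencies
#' and flags a putative selective sweep when one tag's frequency changes
#' monotonically by more than `threshold` (absolute frequency) over any
#' window of at least `window` passages — the signature of a beneficial
#' mutation arising in that tag's genomic background. A passage with zero
#' total count has undefined frequency (`NA`); such passages break monotone
#' windows and are never interpolated across.
#'
#' @param counts data frame with columns `passage`, `count_dtomato`,
#'   `count_gfp` (output of [simulatePassages()] works directly).
#' @param threshold minimum absolute frequency change to flag (default 0.30).
#' @param window minimum number of passages in a monotone window (default 3).
#' @return list: `trajectory` (data frame `passage`, `freq_dtomato`,
#'   `freq_gfp`) and `sweeps` (data frame `tag`, `flagged`, `start`, `end`,
#'   `delta` — the maximal monotone rise found for each tag).
#' @export
tagTrajectorySummary <- function(counts, threshold = 0.30, window = 3) {
  need <- c("passage", "count_dtomato", "count_gfp")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  if (nrow(counts) < 2) stop("counts for at least 2 passages required")
  counts <- counts[order(counts$passage), , drop = FALSE]
  tot <- counts$count_dtomato + counts$count_gfp
  fd <- ifelse(tot > 0, counts$count_dtomato / tot, NA_real_)
  traj <- data.frame(passage = counts$passage, freq_dtomato = fd,
                     freq_gfp = 1 - fd)
  riseScan <- function(f) {
    # maximal rise over non-decreasing runs of >= `window` defined passages
    best <- list(delta = 0, start = NA_real_, end = NA_real_)
    runStart <- 1L
    n <- length(f)
    for (i in seq_len(n)) {
      broken <- i > 1 && (is.na(f[i]) || is.na(f[i - 1]) || f[i] < f[i - 1])
      if (broken) runStart <- i
      len <- i - runStart + 1L
      if (!is.na(f[i]) && len >= window) {
        delta <- f[i] - f[runStart]
        if (delta > best$delta)
          best <- list(delta = delta, start = runStart, end = i)
      }
    }
    best
  }
  sweeps <- do.call(rbind, lapply(c("dTomato", "gfp"), function(tag) {
    f <- if (tag == "dTomato") traj$freq_dtomato else traj$freq_gfp
    b <- riseScan(f)
    data.frame(tag = tag, flagged = b$delta > threshold,
               start = if (is.na(b$start)) NA_real_ else traj$passage[b$start],
               end = if (is.na(b$end)) NA_real_ else traj$passage[b$end],
               delta = b$delta)
  }))
  list(trajectory = traj, sweeps = sweeps)
}
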